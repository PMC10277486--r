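#' K-nearest-neighbor subnetwork of a node
#'
#' Extracts node `i`'s local subnetwork: its K most similar neighbors (self
#' excluded, descending similarity, ties by ascending identifier) plus the
#' node itself, which by convention occupies the LAST position, so that the
#' final coordinate of the label-diffusion row refers to the node's
#' self-weight.  Only positive-similarity neighbors are used; when fewer
#' than K exist, K shrinks for that node (minimum 1 neighbor, falling back
#' to the lowest-identifier other node if the node is fully isolated).
#'
#' @param W a [similarity_network()].
#' @param i node index.
#' @param K neighbor count.
#' @return List with `neighbors` (ordered indices into `W`) and `submatrix`
#'   (`(k+1) x (k+1)`, node `i` last).
#' @export
knn_subnetwork <- function(W, i, K) {
  if (nrow(W) < K + 1L) stop("network must have at least K+1 nodes")
  nbr <- .top_neighbors(W, i, K, positive_only = TRUE)
  if (!length(nbr)) {
    # isolated node: keep the construction well-defined with one neighbor
    nbr <- .top_neighbors(W, i, 1L)
  }
  ver <- c(nbr, i)
  list(neighbors = nbr, submatrix = unclass(W)[ver, ver, drop = FALSE])
}

#' Row-stochastic transition matrix of a subnetwork
#'
#' Divides every row by its sum.  All-zero rows get a unit self-loop first
#' (a node with no outgoing weight diffuses to itself), keeping the matrix
#' stochastic.
#'
#' @param Wi square nonnegative matrix.
#' @return Matrix whose rows sum to 1.
#' @export
transition_matrix <- function(Wi) {
  Wi <- as.matrix(Wi)
  rs <- rowSums(Wi)
  zero <- rs == 0
  if (any(zero)) {
    diag(Wi)[zero] <- 1
    rs <- rowSums(Wi)
  }
  Wi / rs
}

#' Label-diffusion weight row for the subnetwork's own node
#'
#' The converged label-diffusion operator on a subnetwork with transition
#' matrix \eqn{S_i} is \eqn{(1-\alpha)(I-\alpha S_i)^{-1}}.  This returns
#' its LAST row (the row of the node the subnetwork was built around),
#' which expresses the node's converged label as a convex combination of
#' all subnetwork labels: entries are nonnegative and sum to 1.
#'
#' @param Si row-stochastic matrix.
#' @param alpha_diff diffusion constant in (0, 1) (default 0.9).
#' @return Numeric vector of length `nrow(Si)` summing to 1.
#' @export
diffusion_row <- function(Si, alpha_diff = 0.9) {
  if (alpha_diff <= 0 || alpha_diff >= 1)
    stop("alpha_diff must lie in (0, 1)")
  n <- nrow(Si)
  M <- diag(n) - alpha_diff * Si
  e <- numeric(n); e[n] <- 1
  # row n of M^{-1} = solve(t(M), e_n)
  beta <- tryCatch((1 - alpha_diff) * solve(t(M), e),
                   error = function(err)
                     stop("singular diffusion system (condition estimate ",
                          format(kappa(M)), "): ", conditionMessage(err)))
  beta
}

#' Diffusion configuration for the local spectral matrix
#'
#' @param K neighbor count for the per-node subnetworks (default 15).
#' @param alpha_diff diffusion constant in (0, 1) (default 0.9).
#' @return List of class `diffusion_config`.
#' @export
diffusion_config <- function(K = 15L, alpha_diff = 0.9) {
  if (K < 1L) stop("K must be >= 1")
  if (alpha_diff <= 0 || alpha_diff >= 1) stop("alpha_diff must lie in (0, 1)")
  structure(list(K = as.integer(K), alpha_diff = alpha_diff),
            class = "diffusion_config")
}

#' Neighbor reconstruction matrix B via local label diffusion
#'
#' For each node, labels are diffused over its K-nearest-neighbor
#' subnetwork; the node's converged diffusion row \eqn{\beta} is
#' renormalized over the neighbors,
#' \deqn{B_{ij} = \beta_j / (1 - \beta_{K+1}) \quad \text{for } j \in N_i,}
#' (zero elsewhere), so each row of B expresses a node as a convex
#' combination of its neighbors.  If a node's self-weight \eqn{\beta_{K+1}}
#' reaches 1 (node effectively disconnected from its neighbors), its row
#' falls back to the uniform distribution over the neighbor set.
#'
#' @param W a [similarity_network()].
#' @param cfg a [diffusion_config()].
#' @return List of class `vicus_matrix` with `node_ids`, `B`, `vir`
#'   (initially `NULL`; see [vicus_matrix()]), `K`, `alpha_diff`.
#' @export
build_B <- function(W, cfg = diffusion_config()) {
  n <- nrow(W)
  if (cfg$K >= n) stop("K must be smaller than the node count")
  B <- matrix(0, n, n, dimnames = dimnames(W))
  for (i in seq_len(n)) {
    sub <- knn_subnetwork(W, i, cfg$K)
    Si <- transition_matrix(sub$submatrix)
    beta <- diffusion_row(Si, cfg$alpha_diff)
    k <- length(sub$neighbors)
    self_w <- beta[k + 1L]
    if (1 - self_w < 1e-12) {
      B[i, sub$neighbors] <- 1 / k
    } else {
      B[i, sub$neighbors] <- beta[seq_len(k)] / (1 - self_w)
    }
  }
  structure(list(node_ids = rownames(W), B = B, vir = NULL,
                 K = cfg$K, alpha_diff = cfg$alpha_diff),
            class = "vicus_matrix")
}

#' Local spectral (Vicus) matrix
#'
#' Completes a [build_B()] result with \eqn{vir = (I-B)^\top (I-B)}, the
#' local spectral analogue of the graph Laplacian: symmetric, positive
#' semidefinite, with smallest eigenvalue 0 and the all-ones vector in its
#' null space (every B row sums to 1).  The quadratic form
#' \eqn{tr(U^\top vir\, U) = \sum_k \lVert (I-B) U_{:k} \rVert^2}
#' penalizes latent vectors that are poorly reconstructed from their
#' neighbors'.
#'
#' @param x a `vicus_matrix` from [build_B()], or a
#'   [similarity_network()] (in which case `cfg` is used to build B first).
#' @param cfg a [diffusion_config()], used when `x` is a similarity network.
#' @return A `vicus_matrix` with `vir` populated.
#' @examples
#' W <- similarity_network(matrix(runif(64), 8, 8) |> (\(m) (m + t(m)) / 2)())
#' v <- vicus_matrix(W, diffusion_config(K = 3))
#' range(v$vir %*% rep(1, 8))  # numerically zero
#' @export
vicus_matrix <- function(x, cfg = diffusion_config()) {
  if (inherits(x, "similarity_network")) x <- build_B(x, cfg)
  if (!inherits(x, "vicus_matrix")) stop("x must be a vicus_matrix or similarity_network")
  IB <- diag(nrow(x$B)) - x$B
  vir <- crossprod(IB)  # (I-B)'(I-B): symmetric PSD by construction
  dimnames(vir) <- dimnames(x$B)
  x$vir <- vir
  x
}

#' @export
print.vicus_matrix <- function(x, ...) {
  cat(sprintf("vicus_matrix: %d nodes, K = %d, alpha = %g, vir %s\n",
              length(x$node_ids), x$K, x$alpha_diff,
              if (is.null(x$vir)) "not built" else "built"))
  invisible(x)
}

#' Combinatorial Laplacian of the K-nearest-neighbor graph
#'
#' Classical alternative to the Vicus matrix for neighborhood
#' regularization: the K-NN graph (edge kept when either endpoint lists the
#' other among its K nearest) weighted by similarity, returned as
#' \eqn{L = D - W_{knn}}.  Shares the Vicus matrix's contract (symmetric
#' PSD, null vector 1) and can be passed anywhere a `vir` matrix is
#' accepted.
#'
#' @param W a [similarity_network()].
#' @param K neighbor count.
#' @return Symmetric PSD matrix with zero row sums.
#' @export
knn_laplacian <- function(W, K = 15L) {
  n <- nrow(W)
  mask <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    nbr <- .top_neighbors(W, i, K, positive_only = TRUE)
    mask[i, nbr] <- TRUE
  }
  mask <- mask | t(mask)
  Wk <- unclass(W) * mask
  L <- diag(rowSums(Wk)) - Wk
  dimnames(L) <- dimnames(W)
  L
}

#' Write the B matrix as a sparse triplet TSV, and vir as dense TSV
#'
#' @param v a `vicus_matrix`.
#' @param b_path,vir_path output paths (`NULL` to skip either).
#' @return Invisibly, the paths written.
#' @export
write_vicus_tsv <- function(v, b_path = NULL, vir_path = NULL) {
  if (!is.null(b_path)) {
    nz <- which(v$B != 0, arr.ind = TRUE)
    df <- data.frame(i = v$node_ids[nz[, 1L]], j = v$node_ids[nz[, 2L]],
                     value = v$B[nz])
    df <- df[order(df$i, df$j), ]
    utils::write.table(df, b_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(vir_path)) {
    if (is.null(v$vir)) stop("vir not built; call vicus_matrix() first")
    df <- cbind(node_id = v$node_ids,
                as.data.frame(v$vir, check.names = FALSE))
    utils::write.table(df, vir_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(c(b_path, vir_path))
}
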