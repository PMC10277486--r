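#' Nodes with at least one observed interaction
#'
#' During training the latent vectors of metabolites (diseases) with no
#' observed interaction are shaped only by negative samples and are
#' unreliable; these "unknown" nodes get projected latent vectors instead.
#' The known sets are computed from the ORIGINAL binary matrix — after
#' smoothing nearly every row is nonzero and the distinction would vanish.
#'
#' @param A binary [interaction_matrix()].
#' @param axis `"metabolites"` (rows) or `"diseases"` (columns).
#' @return Character vector of identifiers.
#' @export
known_node_set <- function(A, axis = c("metabolites", "diseases")) {
  axis <- match.arg(axis)
  if (axis == "metabolites") rownames(A)[rowSums(unclass(A)) > 0]
  else colnames(A)[colSums(unclass(A)) > 0]
}

#' Neighbor constraint graph for cold-start projection
#'
#' Masks a similarity network to its K-nearest-neighbor structure by the
#' "or" rule: `cons[i, j] = S[i, j]` when i is among j's K nearest
#' neighbors or vice versa, 0 otherwise (diagonal 0).  Symmetric by
#' construction.
#'
#' @param S a [similarity_network()].
#' @param K_proj neighbor count (default 10).
#' @param alpha_decay geometric decay of neighbor weights in (0, 1)
#'   (default 0.9).
#' @return List of class `constraint_graph` with `node_ids`, `cons`,
#'   `K_proj`, `alpha_decay`.
#' @export
build_constraint_graph <- function(S, K_proj = 10L, alpha_decay = 0.9) {
  if (K_proj >= nrow(S)) stop("K_proj must be smaller than the node count")
  if (alpha_decay <= 0 || alpha_decay >= 1)
    stop("alpha_decay must lie in (0, 1)")
  n <- nrow(S)
  mask <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    nbr <- .top_neighbors(S, i, K_proj)
    mask[i, nbr] <- TRUE
  }
  mask <- mask | t(mask)
  diag(mask) <- FALSE
  cons <- unclass(S) * mask
  dimnames(cons) <- dimnames(S)
  structure(list(node_ids = rownames(S), cons = cons,
                 K_proj = as.integer(K_proj), alpha_decay = alpha_decay),
            class = "constraint_graph")
}

#' Project latent vectors of interaction-less nodes onto known neighbors
#'
#' Known nodes keep their trained vectors.  An unknown node i is replaced by
#' \deqn{\bar u_i = \frac{1}{Q_i} \sum_{k=1}^{K} \alpha^{k-1}
#'   \,cons(i, N_i^k)\, u_{N_i^k}, \qquad
#'   Q_i = \sum_{k=1}^{K} \alpha^{k-1}\, cons(i, N_i^k),}
#' where \eqn{N_i^1, \dots, N_i^K} are its K nearest KNOWN nodes by
#' descending constraint weight (ties by ascending identifier).  If no
#' neighbor carries positive weight (Q = 0) the trained vector is kept and
#' a warning is raised.  The projection is idempotent.
#'
#' @param fit a `latent_factors` object from [lmf_fit()].
#' @param graph a [build_constraint_graph()] result over the axis's nodes.
#' @param known character vector of known node identifiers (from
#'   [known_node_set()]).
#' @param axis `"metabolites"` to project `U`, `"diseases"` to project `V`.
#' @return The `latent_factors` with the chosen factor matrix projected.
#' @export
project_latent <- function(fit, graph, known,
                           axis = c("metabolites", "diseases")) {
  axis <- match.arg(axis)
  M <- if (axis == "metabolites") fit$U else fit$V
  ids <- rownames(M)
  if (!identical(ids, graph$node_ids))
    stop("constraint graph does not align with the ", axis, " registry")
  known_idx <- which(ids %in% known)
  S <- graph$cons
  out <- M
  for (i in setdiff(seq_len(nrow(M)), known_idx)) {
    nbr <- .top_neighbors(S, i, graph$K_proj, candidates = known_idx,
                          positive_only = TRUE)
    if (!length(nbr)) {
      warning("no known neighbor with positive weight for '", ids[i],
              "'; trained vector kept")
      next
    }
    w <- graph$alpha_decay^(seq_along(nbr) - 1) * S[i, nbr]
    out[i, ] <- colSums(w * M[nbr, , drop = FALSE]) / sum(w)
  }
  if (axis == "metabolites") fit$U <- out else fit$V <- out
  fit
}

#' Predicted interaction probability for one pair
#'
#' Sigmoid of the (projected) latent inner product for metabolite `i` and
#' disease `j` (indices or identifiers).
#'
#' @param fit a (projected) `latent_factors`.
#' @param i metabolite index or identifier.
#' @param j disease index or identifier.
#' @return Number in (0, 1).
#' @export
predict_pair <- function(fit, i, j) {
  if (is.character(i)) i <- match(i, fit$metabolite_ids)
  if (is.character(j)) j <- match(j, fit$disease_ids)
  if (is.na(i) || is.na(j)) stop("unknown metabolite or disease identifier")
  interaction_probability(fit$U[i, ], fit$V[j, ])
}

#' Predicted probability matrix for all pairs
#'
#' @param fit a (projected) `latent_factors`.
#' @return n x m matrix of probabilities.
#' @export
predict_all <- function(fit) {
  P <- .sigmoid(fit$U %*% t(fit$V))
  dimnames(P) <- list(fit$metabolite_ids, fit$disease_ids)
  P
}

#' Rank metabolites for a disease
#'
#' All metabolites ordered by descending predicted probability (ties by
#' ascending metabolite identifier), each flagged known/unknown against the
#' training matrix.
#'
#' @param fit a (projected) `latent_factors`.
#' @param disease disease identifier.
#' @param A_train the binary training [interaction_matrix()] used to flag
#'   known pairs.
#' @param top_k number of rows to return (default all).
#' @return data.frame with columns `rank`, `metabolite_id`, `probability`,
#'   `known`.
#' @export
rank_for_disease <- function(fit, disease, A_train, top_k = Inf) {
  j <- match(disease, fit$disease_ids)
  if (is.na(j)) stop("unknown disease identifier: ", disease)
  p <- .sigmoid(drop(fit$U %*% fit$V[j, ]))
  ids <- fit$metabolite_ids
  ord <- order(-p, ids)
  k <- min(top_k, length(ord))
  ord <- ord[seq_len(k)]
  data.frame(rank = seq_len(k),
             metabolite_id = ids[ord],
             probability = p[ord],
             known = unclass(A_train)[cbind(ord, j)] > 0,
             row.names = NULL)
}
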