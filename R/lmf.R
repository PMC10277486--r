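#' Model configuration for neighborhood-constrained logistic MF
#'
#' @param c importance weight of observed interactions (>= 1); every
#'   observed pair counts as `c` positive observations (default 2).
#' @param lambda_nbr weight of the local spectral (Vicus) neighborhood
#'   penalty (default 8).
#' @param alpha_reg weight of the Frobenius-norm penalty on the latent
#'   matrices (default 4).
#' @param r latent dimension (default 50; must not exceed min(n, m)).
#' @param max_iter maximum AdaGrad iterations (default 1000).
#' @param learning_rate base AdaGrad step size (default 0.01).
#' @param seed seed for the latent initialization (default 1).
#' @param tol relative-change stopping tolerance on the objective, assessed
#'   over a 10-iteration window (default 1e-6).
#' @param binarize_weights if `TRUE`, the `c`-weighting uses a binarized
#'   copy of the (possibly smoothed) interaction matrix; by default the
#'   smoothed values weight each pair on a continuum between 1 and `c`.
#' @return List of class `lmf_config`.
#' @export
lmf_config <- function(c = 2, lambda_nbr = 8, alpha_reg = 4, r = 50L,
                       max_iter = 1000L, learning_rate = 0.01, seed = 1L,
                       tol = 1e-6, binarize_weights = FALSE) {
  if (c < 1) stop("c must be >= 1")
  if (lambda_nbr < 0 || alpha_reg < 0) stop("penalty weights must be >= 0")
  if (r < 1L) stop("r must be >= 1")
  structure(list(c = c, lambda_nbr = lambda_nbr, alpha_reg = alpha_reg,
                 r = as.integer(r), max_iter = as.integer(max_iter),
                 learning_rate = learning_rate, seed = as.integer(seed),
                 tol = tol, binarize_weights = binarize_weights),
            class = "lmf_config")
}

# log(1 + exp(x)) without overflow
.log1pexp <- function(x) {
  out <- x
  lo <- x <= 0
  out[lo] <- log1p(exp(x[lo]))
  out[!lo] <- x[!lo] + log1p(exp(-x[!lo]))
  out
}

.sigmoid <- function(x) {
  out <- x
  pos <- x >= 0
  out[pos] <- 1 / (1 + exp(-x[pos]))
  ex <- exp(x[!pos])
  out[!pos] <- ex / (1 + ex)
  out
}

#' Interaction probability of a metabolite-disease pair
#'
#' Sigmoid of the latent inner product,
#' \eqn{p = \exp(u \cdot v) / (1 + \exp(u \cdot v))}, computed stably for
#' inner products of any magnitude.
#'
#' @param u,v latent vectors of equal length.
#' @return Number in (0, 1).
#' @export
interaction_probability <- function(u, v) {
  .sigmoid(sum(u * v))
}

#' Penalized log-likelihood of the factorization
#'
#' The Bernoulli log-likelihood with observed pairs up-weighted by `c`,
#' \deqn{\sum_{ij} cA_{ij}\, u_i v_j^\top - (1 + cA_{ij} - A_{ij})
#'   \ln(1 + e^{u_i v_j^\top}),}
#' minus the Frobenius penalty \eqn{\alpha/2 (\lVert U\rVert_F^2 +
#' \lVert V\rVert_F^2)} and the neighborhood penalty
#' \eqn{\lambda/2\,(tr(U^\top vir_u U) + tr(V^\top vir_v V))}.  Training
#' maximizes this quantity (equivalently minimizes its negative).
#'
#' @param U n x r metabolite latent matrix; `V` m x r disease latent matrix.
#' @param V see `U`.
#' @param A interaction matrix (binary or smoothed), n x m.
#' @param vir_u,vir_v local spectral matrices (n x n and m x m), or `NULL`
#'   to drop the corresponding penalty.
#' @param cfg an [lmf_config()].
#' @return Scalar.
#' @export
lmf_objective <- function(U, V, A, vir_u = NULL, vir_v = NULL,
                          cfg = lmf_config()) {
  A <- unclass(A)
  stopifnot(nrow(U) == nrow(A), nrow(V) == ncol(A), ncol(U) == ncol(V))
  X <- U %*% t(V)
  Aw <- if (cfg$binarize_weights) (A > 0) * 1 else A
  cA <- cfg$c * Aw
  w <- 1 + cA - Aw
  ll <- sum(cA * X) - sum(w * .log1pexp(X))
  pen <- cfg$alpha_reg / 2 * (sum(U^2) + sum(V^2))
  if (!is.null(vir_u)) pen <- pen + cfg$lambda_nbr / 2 * sum(U * (vir_u %*% U))
  if (!is.null(vir_v)) pen <- pen + cfg$lambda_nbr / 2 * sum(V * (vir_v %*% V))
  ll - pen
}

#' Gradients of the negative penalized log-likelihood
#'
#' \deqn{\partial L/\partial U = PV + (c-1)(A \odot P)V - cAV +
#'   (\alpha I + \lambda vir_u) U} and symmetrically for V, where
#' \eqn{P = \sigma(UV^\top)} and \eqn{\odot} is the elementwise product.
#' Descent on these gradients maximizes [lmf_objective()].
#'
#' @inheritParams lmf_objective
#' @return `lmf_gradient_U`: n x r matrix; `lmf_gradient_V`: m x r matrix.
#' @export
lmf_gradient_U <- function(U, V, A, vir_u = NULL, cfg = lmf_config()) {
  A <- unclass(A)
  P <- .sigmoid(U %*% t(V))
  Aw <- if (cfg$binarize_weights) (A > 0) * 1 else A
  G <- P %*% V + (cfg$c - 1) * (Aw * P) %*% V - cfg$c * Aw %*% V +
    cfg$alpha_reg * U
  if (!is.null(vir_u)) G <- G + cfg$lambda_nbr * (vir_u %*% U)
  G
}

#' @rdname lmf_gradient_U
#' @export
lmf_gradient_V <- function(U, V, A, vir_v = NULL, cfg = lmf_config()) {
  A <- unclass(A)
  P <- .sigmoid(U %*% t(V))
  Aw <- if (cfg$binarize_weights) (A > 0) * 1 else A
  G <- t(P) %*% U + (cfg$c - 1) * t(Aw * P) %*% U - cfg$c * t(Aw) %*% U +
    cfg$alpha_reg * V
  if (!is.null(vir_v)) G <- G + cfg$lambda_nbr * (vir_v %*% V)
  G
}

#' Fit the neighborhood-constrained logistic matrix factorization
#'
#' AdaGrad descent on the negative penalized log-likelihood from a seeded
#' Gaussian initialization (sd \eqn{1/\sqrt{r}}).  Per-parameter steps are
#' `learning_rate / sqrt(G + 1e-8)` with `G` the accumulated squared
#' gradients.  Training stops when the relative objective change over a
#' 10-iteration window falls below `cfg$tol`, or at `cfg$max_iter`.
#'
#' @inheritParams lmf_objective
#' @param A an [interaction_matrix()] (binary or WKNNP-smoothed).
#' @param vir_u,vir_v `vicus_matrix` objects, plain matrices with the same
#'   contract (e.g. [knn_laplacian()]), or `NULL`.
#' @return List of class `latent_factors`: `U`, `V`, `r`, `config`,
#'   `trace` (objective per iteration, maximized scale), `iterations`,
#'   `metabolite_ids`, `disease_ids`.
#' @export
lmf_fit <- function(A, vir_u = NULL, vir_v = NULL, cfg = lmf_config()) {
  n <- nrow(A); m <- ncol(A)
  if (cfg$r > min(n, m))
    stop("latent dimension r = ", cfg$r, " exceeds min(n, m) = ", min(n, m))
  Vu <- .as_vir(vir_u, n, "vir_u")
  Vv <- .as_vir(vir_v, m, "vir_v")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(cfg$seed)
  U <- matrix(stats::rnorm(n * cfg$r, sd = 1 / sqrt(cfg$r)), n, cfg$r)
  V <- matrix(stats::rnorm(m * cfg$r, sd = 1 / sqrt(cfg$r)), m, cfg$r)
  Gu <- matrix(0, n, cfg$r)
  Gv <- matrix(0, m, cfg$r)
  eps <- 1e-8
  trace <- numeric(0)
  obj <- lmf_objective(U, V, A, Vu, Vv, cfg)
  for (it in seq_len(cfg$max_iter)) {
    gU <- lmf_gradient_U(U, V, A, Vu, cfg)
    gV <- lmf_gradient_V(U, V, A, Vv, cfg)
    Gu <- Gu + gU^2
    Gv <- Gv + gV^2
    U <- U - cfg$learning_rate * gU / sqrt(Gu + eps)
    V <- V - cfg$learning_rate * gV / sqrt(Gv + eps)
    obj <- lmf_objective(U, V, A, Vu, Vv, cfg)
    if (!is.finite(obj))
      stop("training diverged at iteration ", it,
           " (learning_rate = ", cfg$learning_rate, ")")
    trace <- c(trace, obj)
    if (it > 10L) {
      prev <- trace[it - 10L]
      if (abs(obj - prev) < cfg$tol * (abs(prev) + eps)) break
    }
  }
  rownames(U) <- rownames(A)
  rownames(V) <- colnames(A)
  structure(list(U = U, V = V, r = cfg$r, config = cfg, trace = trace,
                 iterations = length(trace),
                 metabolite_ids = rownames(A), disease_ids = colnames(A)),
            class = "latent_factors")
}

#' @export
print.latent_factors <- function(x, ...) {
  cat(sprintf(
    "latent_factors: %d metabolites x %d diseases, r = %d, %d iterations\n",
    nrow(x$U), nrow(x$V), x$r, x$iterations))
  invisible(x)
}

.as_vir <- function(v, n, what) {
  if (is.null(v)) return(NULL)
  if (inherits(v, "vicus_matrix")) {
    if (is.null(v$vir)) stop(what, ": vir not built; call vicus_matrix()")
    v <- v$vir
  }
  v <- as.matrix(v)
  if (nrow(v) != n || ncol(v) != n)
    stop(what, " has dimension ", nrow(v), ", expected ", n)
  v
}

# save/restore the global RNG state so seeded fits do not disturb callers
.Random.seed_save <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Write / read a model checkpoint
#'
#' Flat TSV-based text format: a header section (`key<TAB>value` lines with
#' n, m, r and the config echo), then `U` rows, then `V` rows.
#'
#' @param fit a `latent_factors` object.
#' @param path file path.
#' @return `read_checkpoint` returns a `latent_factors` (without trace).
#' @export
write_checkpoint <- function(fit, path) {
  con <- file(path, "w")
  on.exit(close(con))
  cfg <- fit$config
  hdr <- c(n = nrow(fit$U), m = nrow(fit$V), r = fit$r,
           c = cfg$c, lambda_nbr = cfg$lambda_nbr, alpha_reg = cfg$alpha_reg,
           learning_rate = cfg$learning_rate, seed = cfg$seed)
  writeLines(sprintf("#%s\t%s", names(hdr), format(hdr, digits = 15)), con)
  writeLines(paste(c("id", paste0("f", seq_len(fit$r))), collapse = "\t"), con)
  wr <- function(M, ids) {
    writeLines(paste(ids, apply(format(M, digits = 15, trim = TRUE,
                                       scientific = FALSE),
                                1L, paste, collapse = "\t"), sep = "\t"), con)
  }
  wr(fit$U, fit$metabolite_ids)
  wr(fit$V, fit$disease_ids)
  invisible(path)
}

#' @rdname write_checkpoint
#' @export
read_checkpoint <- function(path) {
  lines <- readLines(path)
  hdr_lines <- grep("^#", lines, value = TRUE)
  hdr <- do.call(rbind, strsplit(sub("^#", "", hdr_lines), "\t"))
  meta <- stats::setNames(as.numeric(trimws(hdr[, 2L])), hdr[, 1L])
  body <- utils::read.table(text = lines[!grepl("^#", lines)], header = TRUE,
                            sep = "\t", stringsAsFactors = FALSE)
  n <- meta[["n"]]; m <- meta[["m"]]; r <- meta[["r"]]
  U <- unname(as.matrix(body[seq_len(n), -1L, drop = FALSE]))
  V <- unname(as.matrix(body[n + seq_len(m), -1L, drop = FALSE]))
  rownames(U) <- body[[1L]][seq_len(n)]
  rownames(V) <- body[[1L]][n + seq_len(m)]
  cfg <- lmf_config(c = meta[["c"]], lambda_nbr = meta[["lambda_nbr"]],
                    alpha_reg = meta[["alpha_reg"]], r = r,
                    learning_rate = meta[["learning_rate"]],
                    seed = as.integer(meta[["seed"]]))
  structure(list(U = U, V = V, r = as.integer(r), config = cfg,
                 trace = numeric(0), iterations = NA_integer_,
                 metabolite_ids = rownames(U), disease_ids = rownames(V)),
            class = "latent_factors")
}
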