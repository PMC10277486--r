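#' Weighted K-nearest-known-neighbor smoothing of the interaction matrix
#'
#' The observed metabolite-disease matrix is extremely sparse; most zeros
#' are unobserved rather than confirmed negatives.  Before factorization the
#' matrix is smoothed by imputing, for every entry, a decayed
#' similarity-weighted average of the profiles of the K most similar
#' metabolites (row side) and diseases (column side), and combining the two
#' sides with the original matrix by elementwise maximum:
#' \deqn{D_{ij} = \max\!\big(Y_{ij},\; (Y^m_{ij} + Y^d_{ij})/2\big),}
#' where the row-side imputation for metabolite \eqn{i} is
#' \deqn{Y^m_{ij} = \frac{1}{Z_i}\sum_{k=1}^{K} \eta^{k-1}\,
#'   SM(i, i_k)\, Y_{i_k j}, \qquad Z_i = \sum_{k=1}^{K} \eta^{k-1}\, SM(i, i_k),}
#' with neighbors \eqn{i_k} ordered by descending similarity (self excluded,
#' ties by ascending identifier) and analogously for diseases.  Observed
#' 1-entries are preserved and the output stays in [0, 1].
#'
#' @param Y an [interaction_matrix()] (typically binary).
#' @param SM metabolite [similarity_network()], aligned with rows of `Y`.
#' @param SD disease [similarity_network()], aligned with columns of `Y`.
#' @param K number of neighbors (default 5).
#' @param eta geometric decay of neighbor weights, in (0, 1) (default 0.9).
#' @param known_only if `TRUE` (default) neighbors are restricted to
#'   rows/columns with at least one known interaction, so imputation only
#'   borrows from profiles that carry information.
#' @return An [interaction_matrix()] with real values in [0, 1], elementwise
#'   at least `Y`.
#' @export
wknnp_smooth <- function(Y, SM, SD, K = 5L, eta = 0.9, known_only = TRUE) {
  if (!identical(rownames(Y), rownames(SM)))
    stop("metabolite identifiers of Y and SM do not align")
  if (!identical(colnames(Y), rownames(SD)))
    stop("disease identifiers of Y and SD do not align")
  if (K < 1L) stop("K must be >= 1")
  if (eta <= 0 || eta >= 1) stop("eta must lie in (0, 1)")
  Ym <- .wknnp_side(unclass(Y), unclass(SM), K, eta, known_only)
  Yd <- t(.wknnp_side(t(unclass(Y)), unclass(SD), K, eta, known_only))
  D <- pmax(unclass(Y), (Ym + Yd) / 2)
  D[D < 0] <- 0
  D[D > 1] <- 1
  interaction_matrix(D, rownames(Y), colnames(Y))
}

# One-sided neighbor-profile imputation over rows of Y; returns the imputed
# matrix (falls back to the original row when no usable neighbor weight).
.wknnp_side <- function(Y, S, K, eta, known_only) {
  out <- Y
  known <- which(rowSums(Y) > 0)
  for (i in seq_len(nrow(Y))) {
    cand <- if (known_only) known else seq_len(nrow(Y))
    nbr <- .top_neighbors(S, i, K, candidates = cand)
    if (!length(nbr)) next
    w <- eta^(seq_along(nbr) - 1) * S[i, nbr]
    Z <- sum(w)
    if (Z <= 0) next  # no similarity mass: row left unchanged
    out[i, ] <- colSums(w * Y[nbr, , drop = FALSE]) / Z
  }
  out
}
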