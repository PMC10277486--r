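#' Cross-validation plan over known interactions
#'
#' Five-fold cross-validation (by default) over the observed 1-entries:
#' each fold's positives are hidden from training, and ALL unobserved pairs
#' of the original matrix serve as test negatives in every fold.
#'
#' @param n_folds number of folds (default 5).
#' @param n_repeats number of independently re-randomized repetitions
#'   (default 20).
#' @param seed master seed; repeat k uses `seed + k - 1`.
#' @return List of class `cv_plan`.
#' @export
cv_plan <- function(n_folds = 5L, n_repeats = 20L, seed = 1L) {
  structure(list(n_folds = as.integer(n_folds),
                 n_repeats = as.integer(n_repeats), seed = as.integer(seed)),
            class = "cv_plan")
}

#' Partition the known interactions into folds
#'
#' Seeded random partition of the 1-entries into `n_folds` groups whose
#' sizes differ by at most one.
#'
#' @param A binary [interaction_matrix()].
#' @param n_folds number of folds.
#' @param seed RNG seed.
#' @return data.frame with columns `row`, `col`, `fold`; one line per
#'   positive entry.
#' @export
make_folds <- function(A, n_folds = 5L, seed = 1L) {
  pos <- which(unclass(A) > 0, arr.ind = TRUE)
  if (nrow(pos) < n_folds)
    stop("need at least ", n_folds, " known interactions, have ", nrow(pos))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  fold <- sample(rep_len(seq_len(n_folds), nrow(pos)))
  data.frame(row = pos[, 1L], col = pos[, 2L], fold = fold)
}

# ---- ranking metrics ------------------------------------------------------

.check_labels <- function(labels) {
  if (!any(labels > 0) || !any(labels <= 0))
    stop("metrics undefined: need at least one positive and one negative label")
}

# Threshold sweep shared by aupr/f1: cumulative TP/FP at each distinct
# score cut (descending), ties grouped.
.pr_points <- function(scores, labels) {
  ord <- order(-scores)
  s <- scores[ord]; y <- labels[ord] > 0
  boundary <- c(diff(s) != 0, TRUE)  # last index of each tie group
  tp <- cumsum(y)[boundary]
  n_at <- seq_along(s)[boundary]
  fp <- n_at - tp
  P <- sum(y)
  list(precision = tp / n_at, recall = tp / P, tp = tp, fp = fp,
       P = P, N = length(y) - P)
}

#' Area under the precision-recall curve
#'
#' Step-wise interpolation: \eqn{\sum_k (R_k - R_{k-1}) P_k} over the
#' distinct score thresholds in descending order (tied scores enter
#' together).
#'
#' @param scores numeric prediction scores.
#' @param labels binary labels (positive = 1 / `TRUE`).
#' @return Number in [0, 1].
#' @export
aupr <- function(scores, labels) {
  .check_labels(labels)
  pts <- .pr_points(scores, labels)
  sum(diff(c(0, pts$recall)) * pts$precision)
}

#' Area under the ROC curve
#'
#' Probability that a random positive outscores a random negative, with
#' ties credited 0.5 (equivalent to the rank-sum / trapezoidal ROC value).
#'
#' @inheritParams aupr
#' @return Number in [0, 1].
#' @export
auc <- function(scores, labels) {
  .check_labels(labels)
  y <- labels > 0
  r <- rank(scores)  # midranks handle ties
  (sum(r[y]) - sum(y) * (sum(y) + 1) / 2) / (sum(y) * sum(!y))
}

#' Best F1 over score thresholds
#'
#' Maximum of \eqn{2PR/(P+R)} over all thresholds of the score ranking
#' (standard for ranking-based interaction prediction).  With
#' `fixed = 0.5` (or any number), classifies at that probability cutoff
#' instead.
#'
#' @inheritParams aupr
#' @param fixed optional fixed threshold; `NULL` (default) maximizes over
#'   thresholds.
#' @return Number in [0, 1].
#' @export
f1_score <- function(scores, labels, fixed = NULL) {
  .check_labels(labels)
  if (!is.null(fixed)) {
    tp <- sum(scores >= fixed & labels > 0)
    fp <- sum(scores >= fixed & labels <= 0)
    fn <- sum(scores < fixed & labels > 0)
    return(if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn))
  }
  pts <- .pr_points(scores, labels)
  max(2 * pts$precision * pts$recall / (pts$precision + pts$recall),
      na.rm = TRUE)
}

# ---- cross-validation -----------------------------------------------------

#' Cross-validated evaluation of the full prediction pipeline
#'
#' For every repeat and fold: zero the held-out positives, smooth the
#' training matrix with [wknnp_smooth()], fit the factorization with the
#' (fold-independent) local spectral matrices, optionally apply the
#' cold-start projection, then score the held-out positives against ALL
#' unobserved pairs of the original matrix and compute AUPR/AUC/F1.
#'
#' @param A binary [interaction_matrix()].
#' @param SM,SD metabolite and disease [similarity_network()]s.
#' @param plan a [cv_plan()].
#' @param cfg an [lmf_config()].
#' @param diff_cfg a [diffusion_config()] for the Vicus matrices.
#' @param wknnp_k,wknnp_eta smoothing parameters (see [wknnp_smooth()]).
#' @param project apply the cold-start projection before scoring
#'   (default `TRUE`).
#' @param K_proj,alpha_decay projection parameters (see
#'   [build_constraint_graph()]).
#' @param regularizer `"vicus"` (default), `"laplacian"`, or `"none"`.
#' @return List of class `metric_report`: `per_fold` (data.frame with
#'   repeat/fold/aupr/auc/f1), `summary` (means and sds), and the echoed
#'   configuration.
#' @export
cross_validate <- function(A, SM, SD, plan = cv_plan(), cfg = lmf_config(),
                           diff_cfg = diffusion_config(),
                           wknnp_k = 5L, wknnp_eta = 0.9,
                           project = TRUE, K_proj = 10L, alpha_decay = 0.9,
                           regularizer = c("vicus", "laplacian", "none")) {
  regularizer <- match.arg(regularizer)
  K_eff <- min(diff_cfg$K, nrow(SM) - 1L, nrow(SD) - 1L)
  dc <- diffusion_config(K_eff, diff_cfg$alpha_diff)
  vir <- switch(regularizer,
    vicus = list(u = vicus_matrix(SM, dc)$vir, v = vicus_matrix(SD, dc)$vir),
    laplacian = list(u = knn_laplacian(SM, K_eff),
                     v = knn_laplacian(SD, K_eff)),
    none = list(u = NULL, v = NULL))
  neg <- which(unclass(A) == 0)
  rows <- list()
  for (rep_i in seq_len(plan$n_repeats)) {
    folds <- make_folds(A, plan$n_folds, seed = plan$seed + rep_i - 1L)
    for (f in seq_len(plan$n_folds)) {
      held <- folds[folds$fold == f, , drop = FALSE]
      A_train <- unclass(A)
      A_train[cbind(held$row, held$col)] <- 0
      stopifnot(all(A_train[cbind(held$row, held$col)] == 0))  # no leakage
      A_train <- interaction_matrix(A_train, rownames(A), colnames(A))
      A_sm <- wknnp_smooth(A_train, SM, SD, K = wknnp_k, eta = wknnp_eta)
      fold_cfg <- cfg
      fold_cfg$seed <- cfg$seed + 1000L * rep_i + f
      fit <- lmf_fit(A_sm, vir$u, vir$v, fold_cfg)
      if (project) {
        kp_m <- min(K_proj, nrow(SM) - 1L)
        kp_d <- min(K_proj, nrow(SD) - 1L)
        fit <- project_latent(fit, build_constraint_graph(SM, kp_m, alpha_decay),
                              known_node_set(A_train, "metabolites"),
                              "metabolites")
        fit <- project_latent(fit, build_constraint_graph(SD, kp_d, alpha_decay),
                              known_node_set(A_train, "diseases"), "diseases")
      }
      P <- predict_all(fit)
      pos_idx <- (held$col - 1L) * nrow(A) + held$row
      scores <- P[c(pos_idx, neg)]
      labels <- c(rep(1L, nrow(held)), rep(0L, length(neg)))
      rows[[length(rows) + 1L]] <- data.frame(
        rep = rep_i, fold = f,
        aupr = aupr(scores, labels),
        auc = auc(scores, labels),
        f1 = f1_score(scores, labels))
    }
  }
  per_fold <- do.call(rbind, rows)
  summary <- data.frame(
    metric = c("aupr", "auc", "f1"),
    mean = vapply(per_fold[c("aupr", "auc", "f1")], mean, numeric(1)),
    sd = vapply(per_fold[c("aupr", "auc", "f1")], stats::sd, numeric(1)),
    row.names = NULL)
  structure(list(per_fold = per_fold, summary = summary, plan = plan,
                 config = cfg, regularizer = regularizer, project = project),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("metric_report: %d repeats x %d folds (%s regularizer)\n",
              x$plan$n_repeats, x$plan$n_folds, x$regularizer))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Grid search over the two regularization weights
#'
#' Evaluates [cross_validate()] at every combination of `alpha_reg` and
#' `lambda_nbr` values and selects the cell with the highest mean AUPR
#' (ties broken toward smaller `lambda_nbr`, then smaller `alpha_reg`).
#' The canonical grid is \eqn{2^{-3}, \dots, 2^{3}} on both axes.
#'
#' @inheritParams cross_validate
#' @param alpha_grid,lambda_grid numeric vectors of candidate weights.
#' @param ... passed on to [cross_validate()].
#' @return List with `surface` (data.frame alpha_reg, lambda_nbr, aupr,
#'   auc, f1) and `best` (the argmax row).
#' @export
grid_search <- function(A, SM, SD, alpha_grid = 2^(-3:3),
                        lambda_grid = 2^(-3:3), plan = cv_plan(),
                        cfg = lmf_config(), ...) {
  if (!length(alpha_grid) || !length(lambda_grid)) stop("empty grid")
  cells <- expand.grid(alpha_reg = alpha_grid, lambda_nbr = lambda_grid)
  res <- lapply(seq_len(nrow(cells)), function(k) {
    cfg_k <- cfg
    cfg_k$alpha_reg <- cells$alpha_reg[k]
    cfg_k$lambda_nbr <- cells$lambda_nbr[k]
    rep <- cross_validate(A, SM, SD, plan = plan, cfg = cfg_k, ...)
    s <- rep$summary
    data.frame(alpha_reg = cells$alpha_reg[k],
               lambda_nbr = cells$lambda_nbr[k],
               aupr = s$mean[s$metric == "aupr"],
               auc = s$mean[s$metric == "auc"],
               f1 = s$mean[s$metric == "f1"])
  })
  surface <- do.call(rbind, res)
  ord <- order(-surface$aupr, surface$lambda_nbr, surface$alpha_reg)
  list(surface = surface, best = surface[ord[1L], , drop = FALSE])
}
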