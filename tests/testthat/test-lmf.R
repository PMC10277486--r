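test_that("interaction probability is a stable sigmoid of the inner product", {
  expect_equal(interaction_probability(c(1, -1), c(1, 1)), 0.5)
  expect_equal(interaction_probability(log(3), 1), 0.75)
  expect_equal(interaction_probability(1e4, 1), 1)
  expect_equal(interaction_probability(-1e4, 1), 0)
  expect_true(is.finite(interaction_probability(5e3, 2)))
})

test_that("objective at zero factors equals the weighted -log(2) count", {
  set.seed(1)
  A <- matrix(rbinom(6, 1, 0.5), 3, 2)
  U <- matrix(0, 3, 2); V <- matrix(0, 2, 2)
  cfg <- lmf_config(c = 2, lambda_nbr = 0, alpha_reg = 0, r = 2)
  expect_equal(lmf_objective(U, V, A, cfg = cfg),
               -sum(1 + cfg$c * A - A) * log(2), tolerance = 1e-12)
  # nonzero penalty lowers the objective
  U1 <- matrix(rnorm(6), 3, 2)
  W <- random_similarity(3, seed = 2)
  vir <- vicus_matrix(W, diffusion_config(K = 1))$vir
  cfg8 <- lmf_config(c = 2, lambda_nbr = 8, alpha_reg = 0, r = 2)
  cfg0 <- lmf_config(c = 2, lambda_nbr = 0, alpha_reg = 0, r = 2)
  if (sum(U1 * (vir %*% U1)) > 0)
    expect_lt(lmf_objective(U1, V, A, vir_u = vir, cfg = cfg8),
              lmf_objective(U1, V, A, vir_u = vir, cfg = cfg0))
})

test_that("objective matches an independent scalar-loop computation", {
  set.seed(3)
  A <- matrix(runif(6), 3, 2)   # smoothed, real-valued
  U <- matrix(rnorm(6), 3, 2)
  V <- matrix(rnorm(4), 2, 2)
  cfg <- lmf_config(c = 2, lambda_nbr = 0, alpha_reg = 0.5, r = 2)
  ref <- 0
  for (i in 1:3) for (j in 1:2) {
    x <- sum(U[i, ] * V[j, ])
    ref <- ref + cfg$c * A[i, j] * x -
      (1 + cfg$c * A[i, j] - A[i, j]) * log(1 + exp(x))
  }
  ref <- ref - cfg$alpha_reg / 2 * (sum(U^2) + sum(V^2))
  expect_equal(lmf_objective(U, V, A, cfg = cfg), ref, tolerance = 1e-10)
})

test_that("with c=1 and no penalties the model is plain Bernoulli logistic MF", {
  set.seed(4)
  A <- matrix(rbinom(6, 1, 0.5), 3, 2)
  U <- matrix(rnorm(6), 3, 2)
  V <- matrix(rnorm(4), 2, 2)
  cfg <- lmf_config(c = 1, lambda_nbr = 0, alpha_reg = 0, r = 2)
  P <- 1 / (1 + exp(-U %*% t(V)))
  bernoulli_ll <- sum(A * log(P) + (1 - A) * log(1 - P))
  expect_equal(lmf_objective(U, V, A, cfg = cfg), bernoulli_ll,
               tolerance = 1e-10)
})

test_that("analytic gradients agree with central differences", {
  worst <- 0
  for (trial in 1:50) {
    set.seed(trial)
    n <- 6; m <- 4; r <- 3
    A <- matrix(runif(n * m) * rbinom(n * m, 1, 0.6), n, m)
    U <- matrix(rnorm(n * r, sd = 0.5), n, r)
    V <- matrix(rnorm(m * r, sd = 0.5), m, r)
    cvals <- c(1, 2, 4); pvals <- c(0, 0.5, 8)
    cfg <- lmf_config(c = sample(cvals, 1),
                      lambda_nbr = sample(pvals, 1),
                      alpha_reg = sample(pvals, 1), r = r)
    vir_u <- vicus_matrix(random_similarity(n, seed = trial),
                          diffusion_config(K = 2))$vir
    vir_v <- vicus_matrix(random_similarity(m, seed = trial + 500),
                          diffusion_config(K = 2))$vir
    # gradients are of the NEGATIVE penalized log-likelihood
    fU <- function(X) -lmf_objective(matrix(X, n, r), V, A, vir_u, vir_v, cfg)
    fV <- function(X) -lmf_objective(U, matrix(X, m, r), A, vir_u, vir_v, cfg)
    gU <- lmf_gradient_U(U, V, A, vir_u, cfg)
    gV <- lmf_gradient_V(U, V, A, vir_v, cfg)
    nU <- matrix(numeric_grad(fU, as.vector(U)), n, r)
    nV <- matrix(numeric_grad(fV, as.vector(V)), m, r)
    relU <- max(abs(gU - nU)) / max(1e-8, max(abs(nU)))
    relV <- max(abs(gV - nV)) / max(1e-8, max(abs(nV)))
    worst <- max(worst, relU, relV)
  }
  expect_lt(worst, 1e-5)
})

test_that("objective is invariant under joint rotation when lambda = 0", {
  set.seed(6)
  A <- matrix(rbinom(12, 1, 0.5), 4, 3)
  U <- matrix(rnorm(8), 4, 2)
  V <- matrix(rnorm(6), 3, 2)
  Q <- qr.Q(qr(matrix(rnorm(4), 2, 2)))   # orthogonal
  cfg <- lmf_config(c = 2, lambda_nbr = 0, alpha_reg = 1.5, r = 2)
  expect_equal(lmf_objective(U %*% Q, V %*% Q, A, cfg = cfg),
               lmf_objective(U, V, A, cfg = cfg), tolerance = 1e-8)
})

test_that("training is deterministic and improves the objective", {
  dat <- generate_bipartite(synthetic_spec(n_metabolites = 12, n_diseases = 8,
                                           seed = 2))
  vu <- vicus_matrix(dat$SM, diffusion_config(K = 4))
  vv <- vicus_matrix(dat$SD, diffusion_config(K = 4))
  cfg <- lmf_config(r = 3, max_iter = 200, learning_rate = 0.05,
                    lambda_nbr = 2, alpha_reg = 0.5, seed = 11)
  f1 <- lmf_fit(dat$A, vu, vv, cfg)
  f2 <- lmf_fit(dat$A, vu, vv, cfg)
  expect_identical(f1$U, f2$U)
  expect_identical(f1$V, f2$V)
  expect_gt(utils::tail(f1$trace, 1), f1$trace[1])  # maximized objective rises
  expect_error(lmf_fit(dat$A, vu, vv, lmf_config(r = 100)), "exceeds")
})

test_that("planted block structure is recovered above chance", {
  spec <- synthetic_spec(n_metabolites = 16, n_diseases = 12,
                         within_block_interaction_prob = 1,
                         background_interaction_prob = 0,
                         noise_flip_prob = 0, seed = 8)
  dat <- generate_bipartite(spec)
  # hide a fifth of the planted pairs, train, check they outrank non-pairs
  pos <- which(unclass(dat$A) == 1)
  set.seed(8)
  held <- sample(pos, length(pos) %/% 5)
  A_train <- unclass(dat$A); A_train[held] <- 0
  A_train <- interaction_matrix(A_train, rownames(dat$A), colnames(dat$A))
  vu <- vicus_matrix(dat$SM, diffusion_config(K = 5))
  vv <- vicus_matrix(dat$SD, diffusion_config(K = 5))
  fit <- lmf_fit(wknnp_smooth(A_train, dat$SM, dat$SD), vu, vv,
                 lmf_config(r = 2, max_iter = 500, learning_rate = 0.05,
                            lambda_nbr = 2, alpha_reg = 0.5))
  P <- predict_all(fit)
  neg <- which(unclass(dat$A) == 0)
  expect_gt(auc(c(P[held], P[neg]),
                c(rep(1, length(held)), rep(0, length(neg)))), 0.9)
})

test_that("a strong neighborhood penalty pulls same-cluster factors together", {
  dat <- generate_bipartite(synthetic_spec(n_metabolites = 16, n_diseases = 12,
                                           similarity_signal = 0.5, seed = 5))
  vu <- vicus_matrix(dat$SM, diffusion_config(K = 4))
  vv <- vicus_matrix(dat$SD, diffusion_config(K = 4))
  fit <- lmf_fit(dat$A, vu, vv,
                 lmf_config(r = 3, max_iter = 500, learning_rate = 0.05,
                            lambda_nbr = 20, alpha_reg = 0.5))
  cos_mat <- function(U) {
    Un <- U / sqrt(rowSums(U^2))
    Un %*% t(Un)
  }
  cm <- cos_mat(fit$U)
  same <- outer(dat$metabolite_blocks, dat$metabolite_blocks, `==`)
  diag(same) <- NA
  expect_gt(mean(cm[same & !is.na(same)]),
            mean(cm[!same & !is.na(same)]))
})

test_that("checkpoints round-trip through the flat text format", {
  dat <- generate_bipartite(synthetic_spec(n_metabolites = 8, n_diseases = 6,
                                           seed = 3))
  fit <- lmf_fit(dat$A, NULL, NULL,
                 lmf_config(r = 2, max_iter = 50, lambda_nbr = 0,
                            alpha_reg = 0.5))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_checkpoint(fit, path)
  back <- read_checkpoint(path)
  expect_equal(back$U, fit$U, tolerance = 1e-12)
  expect_equal(back$V, fit$V, tolerance = 1e-12)
  expect_equal(back$metabolite_ids, fit$metabolite_ids)
  expect_equal(back$config$lambda_nbr, fit$config$lambda_nbr)
})
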