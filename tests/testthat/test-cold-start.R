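make_fit <- function(U, V, mids = NULL, dids = NULL) {
  if (is.null(mids)) mids <- sprintf("m%d", seq_len(nrow(U)))
  if (is.null(dids)) dids <- sprintf("d%d", seq_len(nrow(V)))
  rownames(U) <- mids; rownames(V) <- dids
  structure(list(U = U, V = V, r = ncol(U), config = lmf_config(r = ncol(U)),
                 trace = numeric(0), iterations = 0L,
                 metabolite_ids = mids, disease_ids = dids),
            class = "latent_factors")
}

test_that("known node sets come from the binary matrix", {
  A <- interaction_matrix(matrix(c(1, 0, 0, 0), 2, 2))
  expect_equal(known_node_set(A, "metabolites"), rownames(A)[1])
  expect_equal(known_node_set(A, "diseases"), colnames(A)[1])
  zeros <- interaction_matrix(matrix(0, 2, 2))
  expect_length(known_node_set(zeros, "metabolites"), 0)
  ones <- interaction_matrix(matrix(1, 2, 2))
  expect_equal(known_node_set(ones, "diseases"), colnames(ones))
})

test_that("constraint graph applies a symmetric or-rule K-NN mask", {
  # chain 1-2-3: with K=1 only adjacent pairs survive
  S <- similarity_network(matrix(c(1, 0.9, 0.1,
                                   0.9, 1, 0.8,
                                   0.1, 0.8, 1), 3, 3))
  g <- build_constraint_graph(S, K_proj = 1)
  expect_equal(g$cons[1, 2], 0.9)
  expect_equal(g$cons[2, 3], 0.8)
  expect_equal(g$cons[1, 3], 0)       # neither lists the other
  expect_equal(g$cons, t(g$cons))
  # K = n-1 keeps everything off-diagonal
  gfull <- build_constraint_graph(S, K_proj = 2)
  offdiag <- unclass(S); diag(offdiag) <- 0
  expect_equal(g2 <- gfull$cons, offdiag)
  for (seed in 1:3) {
    Sr <- random_similarity(7, seed = seed)
    gr <- build_constraint_graph(Sr, K_proj = 2)
    expect_equal(gr$cons, t(gr$cons))
  }
})

test_that("projection replaces only unknown nodes, by the decayed formula", {
  U <- rbind(c(1, 0), c(0, 1), c(5, 5))
  V <- matrix(rnorm(4), 2, 2)
  fit <- make_fit(U, V)
  S <- similarity_network(matrix(c(1, 0, 0.8,
                                   0, 1, 0.4,
                                   0.8, 0.4, 1), 3, 3),
                          node_ids = c("m1", "m2", "m3"))
  g <- build_constraint_graph(S, K_proj = 2)
  proj <- project_latent(fit, g, known = c("m1", "m2"), axis = "metabolites")
  expect_equal(proj$U[1, ], fit$U[1, ])   # known: untouched
  expect_equal(proj$U[2, ], fit$U[2, ])
  # m3 unknown: neighbors m1 (0.8) then m2 (0.4), decay 0.9
  w <- c(0.8, 0.9 * 0.4)
  expect_equal(unname(proj$U[3, ]),
               unname((w[1] * U[1, ] + w[2] * U[2, ]) / sum(w)))
  # idempotent
  proj2 <- project_latent(proj, g, known = c("m1", "m2"), axis = "metabolites")
  expect_equal(proj2$U, proj$U)
})

test_that("single-neighbor projection copies the neighbor exactly", {
  U <- rbind(c(2, -1), c(9, 9))
  fit <- make_fit(U, matrix(rnorm(4), 2, 2))
  S <- similarity_network(matrix(c(1, 0.3, 0.3, 1), 2, 2),
                          node_ids = c("m1", "m2"))
  g <- build_constraint_graph(S, K_proj = 1)
  proj <- project_latent(fit, g, known = "m1", axis = "metabolites")
  expect_equal(proj$U[2, ], fit$U[1, ])   # weights cancel
})

test_that("nodes with no usable neighbor keep the trained vector, with warning", {
  U <- rbind(c(1, 1), c(3, 3))
  fit <- make_fit(U, matrix(rnorm(4), 2, 2))
  S <- similarity_network(diag(2) * 1, node_ids = c("m1", "m2"))
  g <- build_constraint_graph(S, K_proj = 1)
  expect_warning(
    proj <- project_latent(fit, g, known = "m1", axis = "metabolites"),
    "trained vector kept")
  expect_equal(proj$U, fit$U)
})

test_that("pair prediction composes projection and the sigmoid", {
  U <- rbind(c(1, 0), c(0, 0))
  V <- rbind(c(2, 0), c(0, 1))
  fit <- make_fit(U, V)
  expect_equal(predict_pair(fit, 1, 1), 1 / (1 + exp(-2)))
  expect_equal(predict_pair(fit, "m2", "d2"), 0.5)
  expect_error(predict_pair(fit, "mX", "d1"), "unknown")
  P <- predict_all(fit)
  expect_equal(P["m1", "d1"], predict_pair(fit, 1, 1))
})

test_that("disease ranking is descending with deterministic tie-break", {
  U <- rbind(c(2, 0), c(1, 0), c(1, 0), c(-3, 0))
  V <- rbind(c(1, 0))
  A <- interaction_matrix(matrix(c(1, 0, 0, 0), 4, 1),
                          sprintf("m%d", 1:4), "d1")
  fit <- make_fit(U, V, sprintf("m%d", 1:4), "d1")
  rk <- rank_for_disease(fit, "d1", A)
  expect_equal(rk$metabolite_id, c("m1", "m2", "m3", "m4"))  # tie m2 < m3
  expect_equal(rk$known, c(TRUE, FALSE, FALSE, FALSE))
  expect_true(all(diff(rk$probability) <= 0))
  expect_equal(nrow(rank_for_disease(fit, "d1", A, top_k = 2)), 2)
  expect_error(rank_for_disease(fit, "dX", A), "unknown disease")
})

test_that("well-fit model ranks a disease's known interactions on top", {
  spec <- synthetic_spec(n_metabolites = 14, n_diseases = 10,
                         within_block_interaction_prob = 1,
                         background_interaction_prob = 0,
                         noise_flip_prob = 0, seed = 12)
  dat <- generate_bipartite(spec)
  fit <- lmf_fit(dat$A, NULL, NULL,
                 lmf_config(r = 2, max_iter = 800, learning_rate = 0.05,
                            lambda_nbr = 0, alpha_reg = 0.1))
  d <- colnames(dat$A)[1]
  rk <- rank_for_disease(fit, d, dat$A)
  n_known <- sum(rk$known)
  expect_true(all(rk$known[seq_len(n_known)]))  # known pairs occupy the top
})
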