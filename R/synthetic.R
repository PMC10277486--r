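#' Specification for synthetic bipartite interaction data
#'
#' Desk-scale data with the statistical structure the factorization model
#' assumes: metabolites and diseases fall into matched blocks, interactions
#' concentrate within matched blocks (low-rank structure), and the block
#' identity is echoed — with tunable strength — in the two similarity
#' networks.
#'
#' @param n_metabolites,n_diseases node counts (defaults 20 and 15).
#' @param n_blocks number of matched blocks (default 2).
#' @param within_block_interaction_prob interaction probability inside a
#'   matched block (default 0.9).
#' @param background_interaction_prob interaction probability elsewhere
#'   (default 0.05).
#' @param noise_flip_prob symmetric label-flip probability (default 0.05).
#' @param similarity_signal difference between within-block and
#'   between-block mean similarity (default 0.45; 0 removes all block
#'   information from the similarity networks).
#' @param seed RNG seed (default 1).
#' @return List of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_metabolites = 20L, n_diseases = 15L,
                           n_blocks = 2L,
                           within_block_interaction_prob = 0.9,
                           background_interaction_prob = 0.05,
                           noise_flip_prob = 0.05,
                           similarity_signal = 0.45, seed = 1L) {
  probs <- c(within_block_interaction_prob, background_interaction_prob,
             noise_flip_prob)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (n_blocks > min(n_metabolites, n_diseases))
    stop("n_blocks must not exceed min(n_metabolites, n_diseases)")
  if (similarity_signal < 0 || similarity_signal > 0.5)
    stop("similarity_signal must lie in [0, 0.5] so similarities stay in [0, 1]")
  structure(list(n_metabolites = as.integer(n_metabolites),
                 n_diseases = as.integer(n_diseases),
                 n_blocks = as.integer(n_blocks),
                 within_block_interaction_prob = within_block_interaction_prob,
                 background_interaction_prob = background_interaction_prob,
                 noise_flip_prob = noise_flip_prob,
                 similarity_signal = similarity_signal,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# Block-structured symmetric similarity matrix: within-block entries have
# mean base + signal, others mean base; truncated-Gaussian jitter; unit
# diagonal.
.block_similarity <- function(labels, signal, ids, base = 0.25, jitter = 0.1) {
  n <- length(labels)
  same <- outer(labels, labels, `==`)
  mu <- base + signal * same
  S <- matrix(0, n, n)
  up <- upper.tri(S)
  S[up] <- mu[up] + stats::rnorm(sum(up), sd = jitter)
  S <- S + t(S)
  S[S < 0] <- 0
  S[S > 1] <- 1
  diag(S) <- 1
  dimnames(S) <- list(ids, ids)
  similarity_network(S)
}

#' Generate a synthetic bipartite interaction dataset
#'
#' Assigns metabolites and diseases to blocks (round-robin), draws
#' interactions Bernoulli(within-prob) inside matched blocks and
#' Bernoulli(background) elsewhere, flips each label with the noise
#' probability, and draws block-structured similarity networks with unit
#' diagonal.  Fully reproducible from the spec's seed.
#'
#' @param spec a [synthetic_spec()].
#' @return List with `A` ([interaction_matrix()], binary), `SM`, `SD`
#'   ([similarity_network()]s), `metabolite_blocks`, `disease_blocks`
#'   (integer ground-truth labels), and `clean_A` (pre-noise matrix).
#' @export
generate_bipartite <- function(spec = synthetic_spec()) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(spec$seed)
  mids <- sprintf("M%03d", seq_len(spec$n_metabolites))
  dids <- sprintf("D%03d", seq_len(spec$n_diseases))
  mb <- rep_len(seq_len(spec$n_blocks), spec$n_metabolites)
  db <- rep_len(seq_len(spec$n_blocks), spec$n_diseases)
  pmat <- ifelse(outer(mb, db, `==`),
                 spec$within_block_interaction_prob,
                 spec$background_interaction_prob)
  clean <- matrix(stats::rbinom(length(pmat), 1L, pmat),
                  spec$n_metabolites, spec$n_diseases,
                  dimnames = list(mids, dids))
  flip <- matrix(stats::rbinom(length(pmat), 1L, spec$noise_flip_prob),
                 spec$n_metabolites, spec$n_diseases)
  A <- abs(clean - flip)
  dimnames(A) <- dimnames(clean)
  SM <- .block_similarity(mb, spec$similarity_signal, mids)
  SD <- .block_similarity(db, spec$similarity_signal, dids)
  list(A = interaction_matrix(A), SM = SM, SD = SD,
       metabolite_blocks = mb, disease_blocks = db,
       clean_A = interaction_matrix(clean))
}

#' Generate a toy rooted term hierarchy
#'
#' A rooted tree of the requested depth and branching factor, with random
#' self counts in 1..5 and optional extra parent edges that create
#' diamond-shaped multiple-inheritance patterns.
#'
#' @param depth tree depth (1 = root only).
#' @param branching children per internal node (default 2).
#' @param seed RNG seed.
#' @param diamond_prob probability that a non-root, non-top-level term gains
#'   a second parent from the level above (default 0).
#' @return A [term_dag()].
#' @export
generate_toy_dag <- function(depth, branching = 2L, seed = 1L,
                             diamond_prob = 0) {
  if (depth < 1L) stop("depth must be >= 1")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  levels <- list("t1")
  counter <- 1L
  edges <- data.frame(child = character(0), parent = character(0))
  for (d in seq_len(depth - 1L)) {
    prev <- levels[[d]]
    lev <- character(0)
    for (p in prev) {
      for (b in seq_len(branching)) {
        counter <- counter + 1L
        id <- paste0("t", counter)
        lev <- c(lev, id)
        edges <- rbind(edges, data.frame(child = id, parent = p))
        if (d > 1L && diamond_prob > 0 &&
            stats::runif(1) < diamond_prob) {
          extra <- sample(prev, 1L)
          if (extra != p)
            edges <- rbind(edges, data.frame(child = id, parent = extra))
        }
      }
    }
    levels[[d + 1L]] <- lev
  }
  terms <- unlist(levels)
  counts <- stats::setNames(sample(1:5, length(terms), replace = TRUE), terms)
  term_dag(edges, counts)
}

#' Generate a toy gene annotation table
#'
#' Random GO term sets per gene (sizes 1..4) and a nonempty random gene set
#' per metabolite.
#'
#' @param n_genes,n_go,n_metabolites counts (all >= 1).
#' @param seed RNG seed.
#' @return A [gene_annotation()].
#' @export
generate_annotations <- function(n_genes, n_go, n_metabolites, seed = 1L) {
  stopifnot(n_genes >= 1, n_go >= 1, n_metabolites >= 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  genes <- sprintf("G%03d", seq_len(n_genes))
  gos <- sprintf("GO%04d", seq_len(n_go))
  gene_go <- do.call(rbind, lapply(genes, function(g) {
    k <- sample(seq_len(min(4L, n_go)), 1L)
    data.frame(gene_id = g, go_id = sample(gos, k))
  }))
  mets <- sprintf("M%03d", seq_len(n_metabolites))
  met_gene <- do.call(rbind, lapply(mets, function(m) {
    k <- sample(seq_len(min(3L, n_genes)), 1L)
    data.frame(metabolite_id = m, gene_id = sample(genes, k))
  }))
  gene_annotation(gene_go, met_gene)
}

#' Write a full set of synthetic inputs as TSV files
#'
#' Emits the interaction edge list plus both similarity matrices in the
#' formats the rest of the package consumes.
#'
#' @param spec a [synthetic_spec()].
#' @param dir output directory (created if missing).
#' @return Invisibly, the generated dataset (as [generate_bipartite()]).
#' @export
write_synthetic_inputs <- function(spec, dir) {
  dat <- generate_bipartite(spec)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_interactions_tsv(dat$A, file.path(dir, "interactions.tsv"), "edges")
  write_similarity_tsv(dat$SM, file.path(dir, "metabolite_similarity.tsv"))
  write_similarity_tsv(dat$SD, file.path(dir, "disease_similarity.tsv"))
  utils::write.table(
    data.frame(metabolite_id = rownames(dat$A), block = dat$metabolite_blocks),
    file.path(dir, "metabolite_blocks.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(disease_id = colnames(dat$A), block = dat$disease_blocks),
    file.path(dir, "disease_blocks.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dat)
}
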