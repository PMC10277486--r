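#' Gene annotation table for metabolite functional similarity
#'
#' Holds per-gene GO term sets and the metabolite-to-gene map from which
#' metabolite functional similarity is computed.  Metabolites mapping to no
#' gene lack functional similarity and are dropped with a message, mirroring
#' the corpus filtering that removes such metabolites.
#'
#' @param gene_go two-column data.frame (gene_id, go_id).
#' @param metabolite_gene two-column data.frame (metabolite_id, gene_id).
#' @return Object of class `gene_annotation` with elements `go_sets` (named
#'   list of character vectors per gene), `metabolite_genes` (named list per
#'   metabolite) and `dropped_metabolites`.
#' @export
gene_annotation <- function(gene_go, metabolite_gene) {
  gene_go <- as.data.frame(gene_go, stringsAsFactors = FALSE)
  metabolite_gene <- as.data.frame(metabolite_gene, stringsAsFactors = FALSE)
  genes <- sort(unique(c(as.character(gene_go[[1L]]),
                         as.character(metabolite_gene[[2L]]))))
  go_sets <- lapply(
    split(as.character(gene_go[[2L]]),
          factor(as.character(gene_go[[1L]]), levels = genes)),
    unique)
  met_genes <- lapply(
    split(as.character(metabolite_gene[[2L]]),
          factor(as.character(metabolite_gene[[1L]]))),
    unique)
  empty <- names(met_genes)[vapply(met_genes, length, 1L) == 0L]
  if (length(empty)) {
    message("dropping metabolites without gene mappings: ",
            paste(empty, collapse = ", "))
    met_genes <- met_genes[setdiff(names(met_genes), empty)]
  }
  structure(list(go_sets = go_sets, metabolite_genes = met_genes,
                 dropped_metabolites = empty),
            class = "gene_annotation")
}

.check_gene <- function(table, g) {
  if (!g %in% names(table$go_sets)) stop("unknown gene: ", g)
  invisible(TRUE)
}

#' Jaccard similarity of two genes' GO annotation sets
#'
#' \eqn{|GO_i \cap GO_j| / |GO_i \cup GO_j|}; defined as 0 when both sets
#' are empty (no evidence of functional similarity).
#'
#' @param a,b gene identifiers.
#' @param table a [gene_annotation()].
#' @return Number in [0, 1].
#' @export
gene_go_jaccard <- function(a, b, table) {
  .check_gene(table, a)
  .check_gene(table, b)
  sa <- table$go_sets[[a]]
  sb <- table$go_sets[[b]]
  u <- length(union(sa, sb))
  if (u == 0L) return(0)
  length(intersect(sa, sb)) / u
}

#' Best-match similarity of a gene against a gene set
#'
#' Maximum GO-Jaccard similarity of `g` over the members of `G`.
#'
#' @param g gene identifier.
#' @param G nonempty character vector of gene identifiers.
#' @inheritParams gene_go_jaccard
#' @return Number in [0, 1].
#' @export
gene_set_similarity <- function(g, G, table) {
  if (!length(G)) stop("gene set G must be nonempty")
  max(vapply(G, function(gj) gene_go_jaccard(g, gj, table), numeric(1)))
}

#' Functional similarity between two metabolites
#'
#' Averages the best-match similarities of each metabolite's genes against
#' the other metabolite's gene set:
#' \deqn{SM(m_1,m_2) = \frac{\sum_{g_1 \in G_1} SG(g_1,G_2) +
#'   \sum_{g_2 \in G_2} SG(g_2,G_1)}{|G_1| + |G_2|}.}
#' Symmetric by construction.
#'
#' @param m1,m2 metabolite identifiers.
#' @inheritParams gene_go_jaccard
#' @return Number in [0, 1].
#' @export
metabolite_similarity <- function(m1, m2, table) {
  G1 <- table$metabolite_genes[[m1]]
  G2 <- table$metabolite_genes[[m2]]
  if (is.null(G1)) stop("metabolite without gene mapping (excluded): ", m1)
  if (is.null(G2)) stop("metabolite without gene mapping (excluded): ", m2)
  s12 <- vapply(G1, function(g) gene_set_similarity(g, G2, table), numeric(1))
  s21 <- vapply(G2, function(g) gene_set_similarity(g, G1, table), numeric(1))
  (sum(s12) + sum(s21)) / (length(G1) + length(G2))
}

#' Pairwise metabolite similarity network
#'
#' @param metabolites metabolite identifiers (default: every mapped
#'   metabolite in the table).
#' @inheritParams gene_go_jaccard
#' @return A [similarity_network()].
#' @export
metabolite_similarity_matrix <- function(table, metabolites = NULL) {
  if (is.null(metabolites)) metabolites <- names(table$metabolite_genes)
  bad <- setdiff(metabolites, names(table$metabolite_genes))
  if (length(bad))
    stop("metabolites without gene mapping: ", paste(bad, collapse = ", "))
  n <- length(metabolites)
  S <- matrix(0, n, n, dimnames = list(metabolites, metabolites))
  for (i in seq_len(n)) {
    for (j in i:n) {
      s <- metabolite_similarity(metabolites[i], metabolites[j], table)
      S[i, j] <- s
      S[j, i] <- s
    }
  }
  similarity_network(S)
}
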