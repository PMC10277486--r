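#' Rooted term hierarchy with annotation counts
#'
#' A `term_dag` holds a rooted directed acyclic graph of disease terms
#' (e.g. a simplified MeSH-style hierarchy) together with a nonnegative
#' annotation count per term.  Term probabilities derived from these counts
#' drive the Lin information-content similarity used to build the
#' disease-disease similarity network.
#'
#' @param parent_edges two-column data.frame or matrix with columns
#'   `child`, `parent` (character term identifiers).
#' @param self_counts named numeric vector of nonnegative annotation counts;
#'   names are term identifiers.  Terms appearing only in `parent_edges`
#'   default to a count of 0.
#'
#' @return An object of class `term_dag` with elements `terms`, `parents`
#'   (list: term -> character vector of direct parents), `children`
#'   (term -> direct children), `self_counts` and `root`.
#' @examples
#' edges <- data.frame(child = c("a", "b"), parent = c("root", "a"))
#' dag <- term_dag(edges, c(root = 1, a = 1, b = 1))
#' term_frequency(dag, "root")
#' @export
term_dag <- function(parent_edges, self_counts) {
  parent_edges <- as.data.frame(parent_edges, stringsAsFactors = FALSE)
  if (ncol(parent_edges) < 2L)
    stop("parent_edges must have two columns (child, parent)")
  child  <- as.character(parent_edges[[1L]])
  parent <- as.character(parent_edges[[2L]])
  terms <- sort(unique(c(child, parent, names(self_counts))))
  counts <- stats::setNames(numeric(length(terms)), terms)
  if (length(self_counts)) {
    if (is.null(names(self_counts)))
      stop("self_counts must be named by term identifier")
    if (any(self_counts < 0)) stop("self_counts must be nonnegative")
    counts[names(self_counts)] <- as.numeric(self_counts)
  }
  parents  <- split(parent, factor(child, levels = terms))
  children <- split(child,  factor(parent, levels = terms))
  roots <- terms[vapply(parents, length, 1L) == 0L]
  if (length(roots) != 1L)
    stop("hierarchy must have exactly one root; found: ",
         paste(roots, collapse = ", "))
  dag <- structure(
    list(terms = terms, parents = parents, children = children,
         self_counts = counts, root = roots),
    class = "term_dag")
  .assert_acyclic(dag)
  dag
}

#' @export
print.term_dag <- function(x, ...) {
  cat(sprintf("term_dag: %d terms, root '%s', total annotations %g\n",
              length(x$terms), x$root, sum(x$self_counts)))
  invisible(x)
}

# Kahn's algorithm; errors on a cycle and on terms unreachable from the root.
.assert_acyclic <- function(dag) {
  indeg <- vapply(dag$children, length, 1L)  # edges child -> parent; process parents last
  # topological order over parent edges: start from leaves (no children)
  queue <- dag$terms[indeg == 0L]
  seen <- 0L
  indeg <- indeg
  while (length(queue)) {
    t <- queue[[1L]]; queue <- queue[-1L]; seen <- seen + 1L
    for (p in dag$parents[[t]]) {
      indeg[[p]] <- indeg[[p]] - 1L
      if (indeg[[p]] == 0L) queue <- c(queue, p)
    }
  }
  if (seen != length(dag$terms))
    stop("cycle detected in term hierarchy")
  reach <- .descendants_or_self(dag, dag$root)
  if (length(reach) != length(dag$terms))
    stop("terms not reachable from the root: ",
         paste(setdiff(dag$terms, reach), collapse = ", "))
  invisible(TRUE)
}

.check_term <- function(dag, t) {
  if (!t %in% dag$terms) stop("unknown term: ", t)
  invisible(TRUE)
}

# Set of t and all terms below it (via child edges), each term once.
.descendants_or_self <- function(dag, t) {
  out <- character(0)
  stack <- t
  while (length(stack)) {
    u <- stack[[length(stack)]]; stack <- stack[-length(stack)]
    if (u %in% out) next
    out <- c(out, u)
    stack <- c(stack, dag$children[[u]])
  }
  out
}

# Ancestors of t including t itself (via parent edges).
.ancestors_or_self <- function(dag, t) {
  out <- character(0)
  stack <- t
  while (length(stack)) {
    u <- stack[[length(stack)]]; stack <- stack[-length(stack)]
    if (u %in% out) next
    out <- c(out, u)
    stack <- c(stack, dag$parents[[u]])
  }
  out
}

#' Term annotation frequency
#'
#' The frequency of a term is its own annotation count plus the counts of
#' everything below it in the hierarchy.  On a DAG a term reachable through
#' several parents is counted once (the frequency is a sum over the
#' descendant *set*), which keeps derived probabilities at or below 1.
#'
#' @param dag a [term_dag()].
#' @param t term identifier.
#' @return Nonnegative number.
#' @export
term_frequency <- function(dag, t) {
  .check_term(dag, t)
  sum(dag$self_counts[.descendants_or_self(dag, t)])
}

#' Term probability
#'
#' Frequency of the term divided by the frequency of the root, so the root
#' always has probability 1 and probabilities are nondecreasing from
#' descendant to ancestor.
#'
#' @inheritParams term_frequency
#' @return Number in (0, 1].
#' @export
term_probability <- function(dag, t) {
  .check_term(dag, t)
  N <- term_frequency(dag, dag$root)
  if (N <= 0) stop("degenerate annotation: root frequency is 0")
  term_frequency(dag, t) / N
}

#' Lin semantic similarity between two terms
#'
#' Information-content similarity
#' \deqn{score(t_1,t_2) = \max_{t \in CA(t_1,t_2)}
#'   \frac{2 \log prob(t)}{\log prob(t_1) + \log prob(t_2)}}
#' maximized over common ancestors.  Because probability is nondecreasing
#' toward the root, the maximum over all common ancestors equals the maximum
#' over least common ancestors.  Identical terms score 1; terms whose only
#' shared ancestor is the root score 0 (the root carries no information).
#' A term with probability 1 (the root itself) scores 0 against any other
#' term and 1 against itself.
#'
#' @inheritParams term_frequency
#' @param t1,t2 term identifiers.
#' @return Number in [0, 1].
#' @export
lin_similarity <- function(dag, t1, t2) {
  .check_term(dag, t1)
  .check_term(dag, t2)
  if (t1 == t2) return(1)
  p1 <- term_probability(dag, t1)
  p2 <- term_probability(dag, t2)
  if (p1 >= 1 || p2 >= 1) return(0)  # root vs anything else: no information
  common <- intersect(.ancestors_or_self(dag, t1), .ancestors_or_self(dag, t2))
  if (!length(common)) return(0)
  pc <- vapply(common, function(t) term_probability(dag, t), numeric(1))
  max(2 * log(pc) / (log(p1) + log(p2)))
}

#' Pairwise disease similarity matrix from a term hierarchy
#'
#' Builds the disease-disease semantic similarity network by evaluating
#' [lin_similarity()] for every disease pair.
#'
#' @inheritParams term_frequency
#' @param diseases character vector of disease term identifiers (must be
#'   terms of the hierarchy).
#' @return A [similarity_network()] over `diseases`.
#' @export
disease_similarity_matrix <- function(dag, diseases) {
  diseases <- as.character(diseases)
  bad <- setdiff(diseases, dag$terms)
  if (length(bad))
    stop("diseases not mapped to hierarchy terms: ", paste(bad, collapse = ", "))
  n <- length(diseases)
  S <- matrix(0, n, n, dimnames = list(diseases, diseases))
  for (i in seq_len(n)) {
    for (j in i:n) {
      s <- lin_similarity(dag, diseases[i], diseases[j])
      S[i, j] <- s
      S[j, i] <- s
    }
  }
  similarity_network(S)
}
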