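#' Symmetric similarity network over one node set
#'
#' Thin validated wrapper around a square symmetric matrix with entries in
#' [0, 1] and node identifiers as dimnames.  Both the metabolite-metabolite
#' and the disease-disease similarity networks are stored this way.
#'
#' @param matrix square numeric matrix; rownames (or `node_ids`) give the
#'   node identifiers.
#' @param node_ids optional character vector of identifiers overriding
#'   the dimnames.
#' @param tol symmetry tolerance.
#' @return Matrix of class `similarity_network`.
#' @export
similarity_network <- function(matrix, node_ids = NULL, tol = 1e-10) {
  matrix <- as.matrix(matrix)
  if (nrow(matrix) != ncol(matrix)) stop("similarity matrix must be square")
  if (is.null(node_ids)) node_ids <- rownames(matrix)
  if (is.null(node_ids)) node_ids <- paste0("n", seq_len(nrow(matrix)))
  if (anyDuplicated(node_ids)) stop("duplicate node identifiers")
  if (length(node_ids) != nrow(matrix))
    stop("node_ids length does not match matrix dimension")
  dimnames(matrix) <- list(node_ids, node_ids)
  if (max(abs(matrix - t(matrix))) > tol)
    stop("similarity matrix is not symmetric within tolerance ", tol)
  matrix <- (matrix + t(matrix)) / 2
  if (min(matrix) < -tol || max(matrix) > 1 + tol)
    stop("similarity values must lie in [0, 1]")
  matrix[matrix < 0] <- 0
  matrix[matrix > 1] <- 1
  structure(matrix, class = c("similarity_network", "matrix", "array"))
}

#' @export
print.similarity_network <- function(x, ...) {
  cat(sprintf("similarity_network: %d nodes, mean off-diagonal %.4f\n",
              nrow(x), mean(x[row(x) != col(x)])))
  invisible(x)
}

#' Fuse several similarity networks by weighted averaging
#'
#' Combines networks over the same node set into one by a renormalized
#' weighted elementwise average.  This is the package's declared fusion rule
#' for multiple disease (or metabolite) similarity sources.
#'
#' @param networks list of [similarity_network()] objects with identical
#'   node identifiers in identical order.
#' @param weights nonnegative numeric vector, one per network, summing to a
#'   positive number.  Default: equal weights.
#' @return A [similarity_network()].
#' @export
fuse_similarities <- function(networks, weights = NULL) {
  if (!length(networks)) stop("need at least one network")
  if (is.null(weights)) weights <- rep(1, length(networks))
  if (length(weights) != length(networks))
    stop("one weight per network required")
  if (any(weights < 0) || sum(weights) <= 0)
    stop("weights must be nonnegative with positive sum")
  ids <- rownames(networks[[1L]])
  for (net in networks[-1L]) {
    if (!identical(rownames(net), ids))
      stop("node sets/orderings of the networks do not match")
  }
  w <- weights / sum(weights)
  fused <- Reduce(`+`, Map(function(net, wi) wi * unclass(net), networks, w))
  similarity_network(fused, node_ids = ids)
}

#' Read / write a similarity network as dense TSV
#'
#' The file has a header row of node identifiers and an identifier column;
#' values are written with full precision (15 significant digits).
#'
#' @param path file path.
#' @return `read_similarity_tsv` returns a [similarity_network()];
#'   `write_similarity_tsv` returns `path` invisibly.
#' @export
read_similarity_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          row.names = 1L)
  similarity_network(as.matrix(df))
}

#' @rdname read_similarity_tsv
#' @param net a [similarity_network()].
#' @export
write_similarity_tsv <- function(net, path) {
  df <- as.data.frame(signif(unclass(net), 15), check.names = FALSE)
  df <- cbind(node_id = rownames(net), df)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
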