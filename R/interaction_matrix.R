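#' Metabolite x disease interaction matrix
#'
#' Binary before smoothing (1 = observed interaction), real-valued in
#' [0, 1] after.  Rows are metabolites, columns diseases; dimnames carry the
#' identifier registries and must align with the similarity networks used
#' alongside.
#'
#' @param values numeric matrix in [0, 1].
#' @param metabolite_ids,disease_ids identifier vectors overriding dimnames.
#' @return Matrix of class `interaction_matrix`.
#' @export
interaction_matrix <- function(values, metabolite_ids = NULL,
                               disease_ids = NULL) {
  values <- as.matrix(values)
  if (is.null(metabolite_ids)) metabolite_ids <- rownames(values)
  if (is.null(disease_ids))    disease_ids <- colnames(values)
  if (is.null(metabolite_ids)) metabolite_ids <- paste0("m", seq_len(nrow(values)))
  if (is.null(disease_ids))    disease_ids <- paste0("d", seq_len(ncol(values)))
  if (anyDuplicated(metabolite_ids) || anyDuplicated(disease_ids))
    stop("duplicate identifiers")
  dimnames(values) <- list(metabolite_ids, disease_ids)
  if (min(values) < 0 || max(values) > 1)
    stop("interaction values must lie in [0, 1]")
  structure(values, class = c("interaction_matrix", "matrix", "array"))
}

#' @export
print.interaction_matrix <- function(x, ...) {
  cat(sprintf("interaction_matrix: %d metabolites x %d diseases, %d nonzero\n",
              nrow(x), ncol(x), sum(x > 0)))
  invisible(x)
}

#' Read / write interaction matrices as TSV
#'
#' Two dialects: `"edges"` — a (metabolite_id, disease_id\[, value\]) edge
#' list, missing pairs are 0; `"dense"` — a full matrix with disease
#' identifiers as header and a metabolite identifier column.
#'
#' @param path file path.
#' @param format `"edges"` or `"dense"`.
#' @param metabolite_ids,disease_ids for `"edges"`, optional full identifier
#'   registries (so all-zero rows/columns survive the round trip).
#' @return `read_interactions_tsv` returns an [interaction_matrix()].
#' @export
read_interactions_tsv <- function(path, format = c("edges", "dense"),
                                  metabolite_ids = NULL, disease_ids = NULL) {
  format <- match.arg(format)
  if (format == "dense") {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            check.names = FALSE, row.names = 1L)
    return(interaction_matrix(as.matrix(df)))
  }
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  df[[1L]] <- as.character(df[[1L]])
  df[[2L]] <- as.character(df[[2L]])
  mets <- if (is.null(metabolite_ids)) sort(unique(df[[1L]])) else metabolite_ids
  dis  <- if (is.null(disease_ids)) sort(unique(df[[2L]])) else disease_ids
  A <- matrix(0, length(mets), length(dis), dimnames = list(mets, dis))
  val <- if (ncol(df) >= 3L) as.numeric(df[[3L]]) else rep(1, nrow(df))
  A[cbind(match(df[[1L]], mets), match(df[[2L]], dis))] <- val
  interaction_matrix(A)
}

#' @rdname read_interactions_tsv
#' @param A an [interaction_matrix()].
#' @export
write_interactions_tsv <- function(A, path, format = c("edges", "dense")) {
  format <- match.arg(format)
  if (format == "dense") {
    df <- cbind(metabolite_id = rownames(A),
                as.data.frame(unclass(A), check.names = FALSE))
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(path))
  }
  nz <- which(unclass(A) != 0, arr.ind = TRUE)
  df <- data.frame(metabolite_id = rownames(A)[nz[, 1L]],
                   disease_id = colnames(A)[nz[, 2L]],
                   value = A[nz])
  df <- df[order(df$metabolite_id, df$disease_id), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Top-K neighbors of node i in similarity matrix S: self excluded,
# descending similarity, ties broken by ascending identifier; restricted to
# `candidates` (indices) when given; only positive-similarity candidates
# when positive_only, shrinking K as needed.
.top_neighbors <- function(S, i, K, candidates = NULL, positive_only = FALSE) {
  ids <- rownames(S)
  cand <- if (is.null(candidates)) seq_len(nrow(S)) else candidates
  cand <- setdiff(cand, i)
  if (positive_only) cand <- cand[S[i, cand] > 0]
  if (!length(cand)) return(integer(0))
  ord <- cand[order(-S[i, cand], ids[cand])]
  ord[seq_len(min(K, length(ord)))]
}
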