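#' Read a term hierarchy from TSV files
#'
#' `hierarchy_path`: two-column TSV (child_term_id, parent_term_id);
#' `annotation_path`: two-column TSV (term_id, self_count).
#'
#' @param hierarchy_path,annotation_path file paths.
#' @return A [term_dag()].
#' @export
read_term_dag_tsv <- function(hierarchy_path, annotation_path) {
  edges <- utils::read.table(hierarchy_path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
  ann <- utils::read.table(annotation_path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  term_dag(edges, stats::setNames(as.numeric(ann[[2L]]),
                                  as.character(ann[[1L]])))
}

#' Read gene annotations from TSV files
#'
#' `gene_go_path`: two-column TSV (gene_id, go_id); `metabolite_gene_path`:
#' two-column TSV (metabolite_id, gene_id).
#'
#' @param gene_go_path,metabolite_gene_path file paths.
#' @return A [gene_annotation()].
#' @export
read_gene_annotation_tsv <- function(gene_go_path, metabolite_gene_path) {
  gene_annotation(
    utils::read.table(gene_go_path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE),
    utils::read.table(metabolite_gene_path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE))
}
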