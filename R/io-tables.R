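# Annotation tables and JSON stage reports.

#' Read a gene annotation table (TSV with columns gene_id, label)
#'
#' @param path TSV file with header columns `gene_id` and `label`.
#' @return a named character vector mapping gene_id to functional label.
#' @export
read_annotation_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("gene_id", "label")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop_format("missing required column '%s' in %s", missing[1], path)
  }
  if (anyDuplicated(df$gene_id)) {
    stop_format("duplicate gene_id '%s' in annotation table %s",
                df$gene_id[duplicated(df$gene_id)][1], path)
  }
  stats::setNames(as.character(df$label), df$gene_id)
}

#' @rdname read_annotation_table
#' @param ann a named label vector as returned by `read_annotation_table`.
#' @param gene_ids genes to look up; unknown genes get `"unlabeled"`.
#' @export
annotation_label <- function(ann, gene_ids) {
  out <- unname(ann[gene_ids])
  out[is.na(out)] <- "unlabeled"
  out
}

#' @rdname read_annotation_table
#' @export
write_annotation_table <- function(ann, path) {
  utils::write.table(data.frame(gene_id = names(ann), label = unname(ann)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a machine-readable JSON stage report
#'
#' Stage drivers record their parameters, seeds and headline counts as JSON
#' so that runs are auditable and reloadable.
#'
#' @param x a named list.
#' @param path output path.
#' @export
write_report_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_report_json
#' @export
read_report_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
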