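#' Read an expression dataset from TSV files
#'
#' The expression file is tab-separated with transcript ids in the first
#' column and one column per sample. The metadata file has columns
#' `sample_id`, `group` and optionally `is_true_outlier`.
#'
#' @param expr_path Path to the expression TSV.
#' @param meta_path Path to the sample-metadata TSV.
#' @param counts If `TRUE` the matrix is treated as raw counts and passed
#'   through [logcpm_transform()].
#'
#' @return An `expression_dataset`.
#' @export
read_expression_dataset <- function(expr_path, meta_path, counts = FALSE) {
  ex <- readr::read_tsv(expr_path, show_col_types = FALSE, progress = FALSE)
  meta <- readr::read_tsv(meta_path, show_col_types = FALSE, progress = FALSE)
  mat <- as.matrix(ex[, -1, drop = FALSE])
  rownames(mat) <- as.character(ex[[1]])
  meta <- meta[match(colnames(mat), meta$sample_id), ]
  if (anyNA(meta$sample_id)) {
    ob_abort("metadata is missing entries for some expression columns", "input")
  }
  if (counts) mat <- logcpm_transform(mat)
  expression_dataset(mat, meta)
}

#' Write an expression dataset to TSV files
#'
#' @param ds An `expression_dataset`.
#' @param expr_path,meta_path Output paths.
#' @return `ds`, invisibly.
#' @export
write_expression_dataset <- function(ds, expr_path, meta_path) {
  stopifnot(inherits(ds, "expression_dataset"))
  ex <- tibble(transcript_id = rownames(ds$expr))
  ex <- dplyr::bind_cols(ex, as_tibble(ds$expr))
  readr::write_tsv(ex, expr_path, progress = FALSE)
  readr::write_tsv(ds$samples, meta_path, progress = FALSE)
  invisible(ds)
}
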