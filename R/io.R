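# Plain-text readers/writers for the pipeline's interchange formats:
# feature x sample TSV with a feature_id (and optional gene_symbol) column,
# sample-metadata TSV, single-cell CSV, long-format track CSV, and a JSON
# ground-truth document.

#' Write a feature x sample matrix as TSV
#'
#' @param assay list with `values` and `features` (as produced by
#'   [generate_multiomic()]), or a plain matrix.
#' @param path output file.
#' @export
write_assay_tsv <- function(assay, path) {
  if (is.matrix(assay)) {
    df <- data.frame(feature_id = rownames(assay), assay,
                     check.names = FALSE, stringsAsFactors = FALSE)
  } else {
    df <- data.frame(feature_id = assay$features$feature_id,
                     gene_symbol = assay$features$gene_symbol,
                     assay$values, check.names = FALSE,
                     stringsAsFactors = FALSE)
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a feature x sample TSV
#'
#' @param path TSV written by [write_assay_tsv()].
#' @return List with `values` matrix and `features` data.frame.
#' @export
read_assay_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  meta_cols <- intersect(c("feature_id", "gene_symbol"), names(df))
  vals <- as.matrix(df[, setdiff(names(df), meta_cols), drop = FALSE])
  rownames(vals) <- df$feature_id
  list(values = vals, features = df[, meta_cols, drop = FALSE])
}

#' Write/read the sample-metadata sidecar
#' @param meta design table from [generate_design()].
#' @param path TSV path.
#' @export
write_meta_tsv <- function(meta, path) {
  write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname write_meta_tsv
#' @export
read_meta_tsv <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

#' Write/read single-cell tables and lineage tracks as CSV
#' @param x cell table or long track table.
#' @param path CSV path.
#' @export
write_cells_csv <- function(x, path) write.csv(x, path, row.names = FALSE)

#' @rdname write_cells_csv
#' @export
read_cells_csv <- function(path) read.csv(path, stringsAsFactors = FALSE)

#' Write/read the ground-truth document as JSON
#' @param truth `truth` element from [generate_multiomic()].
#' @param path JSON path.
#' @export
write_truth_json <- function(truth, path) {
  doc <- list(feature_modules = truth$feature_modules,
              profiles = if (!is.null(truth$profiles))
                list(values = truth$profiles,
                     modules = rownames(truth$profiles),
                     conditions = colnames(truth$profiles)),
              covariate_fractions = truth$covariate_fractions,
              realized_fractions = truth$realized_fractions)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
}

#' @rdname write_truth_json
#' @export
read_truth_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(doc$profiles)) {
    prof <- as.matrix(doc$profiles$values)
    dimnames(prof) <- list(doc$profiles$modules, doc$profiles$conditions)
    doc$profiles <- prof
  }
  doc
}

#' Write a long differential table / scaled matrix to TSV
#' @param x data.frame or `scaled_matrix`.
#' @param path TSV path.
#' @export
write_table_tsv <- function(x, path) {
  if (inherits(x, "scaled_matrix"))
    x <- data.frame(feature_id = rownames(x$values), x$values,
                    check.names = FALSE, stringsAsFactors = FALSE)
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
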