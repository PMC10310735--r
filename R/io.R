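# Canonical on-disk formats: TSV matrices (rows = features, header = sample
# ids, "NA" for missing), CSV clinical tables, GMT gene sets, JSON results.

#' Read a feature-by-sample matrix from TSV
#'
#' First column holds feature identifiers (must be unique), remaining
#' columns one sample each; missing values as empty fields or "NA".
#'
#' @param path TSV file.
#' @return Numeric matrix with feature rownames and sample colnames.
#' @export
read_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE, na.strings = c("NA", ""))
  assert_that(ncol(df) >= 2, "matrix file needs an id column and >= 1 sample")
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) {
    stop("duplicate feature identifier at line ",
         which(duplicated(ids))[1] + 1, call. = FALSE)
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  m
}

#' Write a feature-by-sample matrix as TSV
#'
#' @param matrix numeric matrix with dimnames.
#' @param path output file.
#' @param id_column header for the identifier column (default "feature").
#' @export
write_matrix <- function(matrix, path, id_column = "feature") {
  assert_matrix(matrix, "matrix")
  df <- data.frame(rownames(matrix), matrix, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
}

#' Read a clinical annotation table from CSV
#'
#' @param path CSV file with a `sample` column (unique identifiers).
#' @return `data.frame`.
#' @export
read_clinical <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  assert_that("sample" %in% names(df), "clinical table needs a 'sample' column")
  assert_that(!anyDuplicated(df$sample), "duplicate sample identifiers")
  df
}

#' Write a clinical annotation table as CSV
#'
#' @param clinical `data.frame` with a `sample` column.
#' @param path output file.
#' @export
write_clinical <- function(clinical, path) {
  utils::write.csv(clinical, path, row.names = FALSE, quote = FALSE)
}
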