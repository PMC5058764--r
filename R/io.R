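# Readers and writers for the cohort CSV, expression TSV/MTX and result
# tables. Booleans travel as 0/1, missing values as empty fields.

cohort_logical_cols <- c("epe", "svi", "positive_margins", "recurrence")

#' Read a patient cohort CSV
#'
#' One row per patient; required columns `case_id`, `serum_psa`,
#' `prostate_volume`, `total_tumour_volume`; boolean columns (`epe`, `svi`,
#' `positive_margins`, `recurrence`) coded 0/1; missing values as empty
#' fields. Malformed rows raise an error naming the offending line.
#'
#' @param path Path to a CSV file.
#' @return A typed tibble of patient records.
#' @export
read_cohort_csv <- function(path) {
  headers <- names(readr::read_csv(path, n_max = 0, show_col_types = FALSE))
  typed <- list(case_id = readr::col_character(),
                stage = readr::col_character(),
                gleason_primary = readr::col_integer(),
                gleason_secondary = readr::col_integer())
  spec <- do.call(readr::cols,
                  c(typed[intersect(names(typed), headers)],
                    list(.default = readr::col_double())))
  x <- readr::read_csv(path, col_types = spec, na = c("", "NA"))
  probs <- readr::problems(x)
  if (nrow(probs) > 0) {
    stop_tpsad(sprintf("Malformed cohort CSV: %s at line %d.",
                       probs$expected[1], probs$row[1]), "tpsad_io_error")
  }
  check_columns(x, c("case_id", "serum_psa", "prostate_volume", "total_tumour_volume"),
                basename(path))
  if (nrow(x) == 0) warn(sprintf("'%s' contains a header but no records.", basename(path)))
  for (col in intersect(cohort_logical_cols, names(x))) x[[col]] <- as_flag(x[[col]])
  x
}

#' Write a patient cohort CSV
#'
#' Inverse of [read_cohort_csv()]: logical columns are written as 0/1 and
#' missing values as empty fields, so `read_cohort_csv(write_cohort_csv(x))`
#' round-trips exactly.
#'
#' @param cohort Cohort tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  out <- cohort
  for (col in intersect(cohort_logical_cols, names(out))) {
    out[[col]] <- as.integer(out[[col]])
  }
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' Write a result table as TSV with provenance header
#'
#' Prepends `# seed=` / `# config_hash=` comment lines (when supplied) so
#' every output table records how it was produced; list-columns are dropped
#' with a note since TSV cannot carry them.
#'
#' @param x Data frame.
#' @param path Output path.
#' @param seed,config_hash Optional provenance fields.
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path, seed = NULL, config_hash = NULL) {
  is_list <- vapply(x, is.list, logical(1))
  if (any(is_list)) x <- x[!is_list]
  header <- c(
    if (!is.null(seed)) sprintf("# seed=%s", seed),
    if (!is.null(config_hash)) sprintf("# config_hash=%s", config_hash)
  )
  if (length(header)) writeLines(header, path)
  readr::write_tsv(x, path, append = length(header) > 0, col_names = TRUE)
  invisible(path)
}

#' Read an expression matrix TSV
#'
#' Genes in rows, samples in columns, first column the gene identifier.
#'
#' @param path Path to a TSV file.
#' @return Numeric matrix with gene rownames.
#' @export
read_expression_tsv <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, comment = "#")
  genes <- x[[1]]
  m <- as.matrix(x[-1])
  if (!is.numeric(m)) stop_tpsad("Expression values must be numeric.", "tpsad_io_error")
  rownames(m) <- genes
  m
}

#' Write an expression matrix TSV
#' @param values Numeric matrix with gene rownames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(values, path) {
  df <- tibble::as_tibble(values, rownames = "gene")
  readr::write_tsv(df, path)
  invisible(path)
}

#' Read a sample-label TSV
#'
#' Two columns: `sample`, `class` (values `high_grade` / `comparator`).
#'
#' @param path Path to a TSV file.
#' @return A tibble with columns `sample` and `class`.
#' @export
read_labels_tsv <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, comment = "#")
  check_columns(x, c("sample", "class"), basename(path))
  x
}

#' Read a count matrix in MatrixMarket triplet form
#'
#' `path` is the `.mtx` file; `genes_path` and `samples_path` are plain-text
#' sidecars with one row/column name per line.
#'
#' @param path,genes_path,samples_path File paths.
#' @return Dense numeric count matrix with dimnames.
#' @export
read_counts_mtx <- function(path, genes_path, samples_path) {
  m <- as.matrix(Matrix::readMM(path))
  genes <- readLines(genes_path)
  samples <- readLines(samples_path)
  if (nrow(m) != length(genes) || ncol(m) != length(samples)) {
    stop_tpsad("MTX dimensions do not match the row/column name sidecars.", "tpsad_io_error")
  }
  dimnames(m) <- list(genes, samples)
  m
}
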