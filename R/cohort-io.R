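#' Read and write cohort tables
#'
#' Cohort tables are exchanged as wide CSV (comma-separated, UTF-8, header
#' row, empty cell = missing): one row per subject with metadata columns
#' followed by `pep_*` peptide abundance columns. Reading is header-driven;
#' any column whose name starts with `pep_` is treated as a peptide.
#'
#' @param path File path.
#' @return `read_cohort()` returns a `cohort_table` data frame.
#' @section Errors:
#' Duplicate subject IDs, non-numeric peptide cells (named by row and
#' column) and peptide columns with no observed values are reported as
#' parse errors.
#' @export
read_cohort <- function(path) {
  raw <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                  na.strings = "")
  assert_that("subject_id" %in% names(raw), "missing subject_id column")
  dup <- raw$subject_id[duplicated(raw$subject_id)]
  if (length(dup) > 0) {
    stop(sprintf("duplicate subject_id: %s",
                 paste(unique(dup), collapse = ", ")), call. = FALSE)
  }
  pep_cols <- grep("^pep_", names(raw), value = TRUE)
  for (cl in pep_cols) {
    v <- raw[[cl]]
    if (is.character(v)) {
      num <- suppressWarnings(as.numeric(v))
      bad <- which(!is.na(v) & is.na(num))
      if (length(bad) > 0) {
        stop(sprintf("non-numeric peptide value in column %s, row %d ('%s')",
                     cl, bad[1], v[bad[1]]), call. = FALSE)
      }
      raw[[cl]] <- num
    }
    if (nrow(raw) > 0 && all(is.na(raw[[cl]]))) {
      stop(sprintf("peptide column with no observed values: %s", cl),
           call. = FALSE)
    }
  }
  num_cols <- intersect(c("age", "education", "moca", "abeta42", "ttau",
                          "ptau", "av45_suvr", "fdg_suvr"), names(raw))
  for (cl in num_cols) raw[[cl]] <- as.numeric(raw[[cl]])
  class(raw) <- c("cohort_table", "data.frame")
  raw
}

#' @rdname read_cohort
#' @param table A `cohort_table` data frame.
#' @return `write_cohort()` returns `path` invisibly.
#' @export
write_cohort <- function(table, path) {
  write.csv(as.data.frame(table), path, row.names = FALSE, na = "")
  invisible(path)
}
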