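#' Read and write patient-level cohort tables
#'
#' The interchange format is a comma-delimited, UTF-8 CSV with header
#' `id, arm, t_recurrence, event_recurrence, t_death, event_death, t_censor,
#' transplant, cost_stable, cost_recurrence`; times in years, costs in Euro,
#' booleans as 0/1, missing values as empty fields. Floating-point values are
#' written with 6 significant digits.
#'
#' @param cohort a cohort `data.frame`.
#' @param path file path.
#' @return `read_cohort` returns the validated cohort `data.frame`;
#'   `write_cohort` returns `path` invisibly.
#' @export
write_cohort <- function(cohort, path) {
  validate_cohort(cohort)
  out <- cohort[cohort_columns]
  num <- vapply(out, is.numeric, TRUE) & !vapply(out, is.integer, TRUE)
  out[num] <- lapply(out[num], signif, digits = 6)
  write.csv(out, path, row.names = FALSE, na = "", quote = FALSE,
            fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop_param("cohort file not found: ", path)
  d <- read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  missing_cols <- setdiff(cohort_columns, names(d))
  if (length(missing_cols))
    stop_param("malformed cohort CSV '", path, "': missing column(s) ",
               paste(missing_cols, collapse = ", "))
  for (col in c("t_recurrence", "t_death", "t_censor", "cost_stable", "cost_recurrence")) {
    if (!is.numeric(d[[col]]))
      stop_param("malformed cohort CSV '", path, "': column '", col, "' is not numeric")
  }
  for (col in c("event_recurrence", "event_death", "transplant")) {
    if (!all(d[[col]] %in% c(0L, 1L)))
      stop_param("malformed cohort CSV '", path, "': column '", col,
                 "' must be 0/1 (first bad row: ",
                 which(!d[[col]] %in% c(0L, 1L))[1], ")")
  }
  validate_cohort(d)
  d
}
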