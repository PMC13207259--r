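#' Write / read a cohort dataset as delimited text
#'
#' A dataset directory holds `patients.csv`, `claims.csv` and
#' `enrollment.csv`. Dates are rendered as ISO-8601 calendar dates on
#' disk and converted back to integer day offsets on read, so
#' `read_dataset(write_dataset(x))` reproduces the in-memory tables.
#'
#' @param cohort a `ted_cohort` (or list with `patients`, `claims`,
#'   `enrollment`).
#' @param path directory to create/fill.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(cohort, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  p <- cohort$patients
  p$index_date <- as.character(day_as_date(p$index_date))
  e <- cohort$enrollment
  e$span_start <- as.character(day_as_date(e$span_start))
  e$span_end <- as.character(day_as_date(e$span_end))
  cl <- cohort$claims
  cl$service_date <- as.character(day_as_date(cl$service_date))
  data.table::fwrite(p, file.path(path, "patients.csv"))
  data.table::fwrite(cl, file.path(path, "claims.csv"))
  data.table::fwrite(e, file.path(path, "enrollment.csv"))
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  need <- file.path(path, c("patients.csv", "claims.csv", "enrollment.csv"))
  missing <- need[!file.exists(need)]
  if (length(missing)) stop_input("missing dataset files: %s", paste(missing, collapse = ", "))
  p <- tibble::as_tibble(data.table::fread(need[1], colClasses = list(character = "patient_id")))
  cl <- tibble::as_tibble(data.table::fread(need[2], colClasses = list(character = c("patient_id", "code", "system"))))
  e <- tibble::as_tibble(data.table::fread(need[3], colClasses = list(character = "patient_id")))
  if (nrow(cl)) {
    bad <- which(!cl$system %in% CODE_SYSTEMS)
    if (length(bad)) {
      stop_input("claims.csv row %d: unknown code system '%s'", bad[1], cl$system[bad[1]])
    }
  }
  p$index_date <- as_day(p$index_date)
  cl$service_date <- if (nrow(cl)) as_day(cl$service_date) else integer(0)
  e$span_start <- as_day(e$span_start)
  e$span_end <- as_day(e$span_end)
  structure(list(patients = p, claims = cl, enrollment = e, config = NULL),
            class = "ted_cohort")
}
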