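#' Write and read cohort tables
#'
#' Cohorts round-trip through two plain CSV files, `mice.csv` and
#' `assessments.csv`, with missing values encoded as empty fields and dates
#' as ISO-8601. `read_cohort()` validates scores against the catalog and
#' rejects malformed files, out-of-range deficit scores, and duplicate
#' (mouse_id, date) rows, naming the offending row.
#'
#' @param cohort An `fgi_cohort` or a list with tibbles `mice` and
#'   `assessments`.
#' @param path Directory to write to / read from (created if absent).
#' @param catalog Deficit catalog used for validation on read.
#' @return `write_cohort()` returns the file paths invisibly;
#'   `read_cohort()` returns a list with `mice` and `assessments` tibbles.
#' @export
write_cohort <- function(cohort, path) {
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  files <- c(mice = file.path(path, "mice.csv"),
             assessments = file.path(path, "assessments.csv"))
  readr::write_csv(cohort$mice, files["mice"], na = "")
  readr::write_csv(cohort$assessments, files["assessments"], na = "")
  invisible(files)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path, catalog = deficit_catalog()) {
  check_catalog(catalog)
  mf <- file.path(path, "mice.csv")
  af <- file.path(path, "assessments.csv")
  for (f in c(mf, af)) {
    if (!file.exists(f)) abort(sprintf("cohort file not found: %s", f))
  }
  mice <- readr::read_csv(
    mf, na = "",
    col_types = readr::cols(
      mouse_id = readr::col_character(), strain = readr::col_character(),
      sex = readr::col_character(), diet = readr::col_character(),
      enrollment_age_days = readr::col_double(),
      lifespan_days = readr::col_double()
    )
  )
  check_columns(mice, c("mouse_id", "strain", "sex", "diet",
                        "enrollment_age_days", "lifespan_days"), "mice.csv")

  assessments <- readr::read_csv(
    af, na = "",
    col_types = readr::cols(
      mouse_id = readr::col_character(), date = readr::col_date(),
      .default = readr::col_double()
    )
  )
  check_columns(assessments,
                c("mouse_id", "date", "age_days", "weight_g", "temp_C",
                  catalog$column),
                "assessments.csv")
  validate_assessments(assessments, catalog)
  list(mice = mice, assessments = assessments)
}

validate_assessments <- function(assessments, catalog) {
  dup <- duplicated(assessments[c("mouse_id", "date")])
  if (any(dup)) {
    abort(sprintf("duplicate (mouse_id, date) at row %d: %s %s",
                  which(dup)[1], assessments$mouse_id[which(dup)[1]],
                  format(assessments$date[which(dup)[1]])))
  }
  for (j in seq_len(nrow(catalog))) {
    x <- assessments[[catalog$column[j]]]
    ok <- is.na(x) | x %in% valid_scores(catalog$n_levels[j])
    if (!all(ok)) {
      abort(sprintf(
        "invalid score %s for %d-level item '%s' at row %d",
        format(x[which(!ok)[1]]), catalog$n_levels[j], catalog$column[j],
        which(!ok)[1]
      ))
    }
  }
  invisible(assessments)
}
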