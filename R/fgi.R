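#' Score assessments with the Fragility Index
#'
#' The FgI score for an assessment is the mean deficit level across all
#' ordinally scored items that were observed, yielding a value between 0 and
#' 1 (1 = maximum deficit in every item). Missing items are dropped from the
#' denominator — no imputation — so the score is defined throughout periods
#' when an item was not yet collected. A deficit is counted as severe when it
#' is at its maximum level (score 1 for both two- and three-level items).
#'
#' @param assessments Assessment table with one column per catalog item.
#' @param catalog Deficit catalog, see [deficit_catalog()].
#' @return A tibble with `mouse_id`, `date`, `fgi_score` (NA when no item was
#'   observed), `n_items_observed`, and `n_severe`.
#' @examples
#' cohort <- simulate_cohort(cohort_config(n_mice_per_group = 2))
#' fgi <- fgi_score(cohort$assessments)
#' summary(fgi$fgi_score)
#' @export
fgi_score <- function(assessments, catalog = deficit_catalog()) {
  check_catalog(catalog)
  check_columns(assessments, c("mouse_id", "date", catalog$column),
                "assessments")
  validate_assessments(assessments, catalog)
  m <- as.matrix(assessments[catalog$column])
  n_obs <- rowSums(!is.na(m))
  tibble::tibble(
    mouse_id = assessments$mouse_id,
    date = assessments$date,
    fgi_score = ifelse(n_obs > 0, rowMeans(m, na.rm = TRUE), NA_real_),
    n_items_observed = as.integer(n_obs),
    n_severe = as.integer(rowSums(m == 1, na.rm = TRUE))
  )
}

#' Per-item cumulative incidence of severe deficits
#'
#' For each deficit and cohort group, the proportion of mice whose maximum
#' observed score over follow-up equals the item's maximum possible level.
#' Cumulative incidence reveals ceiling and floor effects in the deficit
#' scale: items no mouse ever reaches (floor) and items nearly every mouse
#' eventually shows (ceiling).
#'
#' @param assessments Assessment table.
#' @param mice Mouse table (for group labels).
#' @param catalog Deficit catalog.
#' @param group_by Character vector of mouse-level grouping columns.
#' @return Tibble with group columns, `item`, `n_mice`, and
#'   `cumulative_incidence`; items never observed in a group have incidence 0
#'   computed over the mice with at least one observation (NA if none).
#' @export
cumulative_incidence <- function(assessments, mice,
                                 catalog = deficit_catalog(),
                                 group_by = "strain") {
  check_catalog(catalog)
  check_columns(mice, c("mouse_id", group_by), "mice")
  joined <- dplyr::inner_join(
    assessments, dplyr::select(mice, dplyr::all_of(c("mouse_id", group_by))),
    by = "mouse_id"
  )
  if (nrow(joined) == 0) abort("no assessments joined to mice")
  long <- joined |>
    dplyr::select(dplyr::all_of(c("mouse_id", group_by, catalog$column))) |>
    tidyr::pivot_longer(dplyr::all_of(catalog$column),
                        names_to = "column", values_to = "score") |>
    dplyr::filter(!is.na(.data$score))
  long |>
    dplyr::summarise(max_score = max(.data$score),
                     .by = dplyr::all_of(c("mouse_id", group_by, "column"))) |>
    dplyr::summarise(
      n_mice = dplyr::n(),
      cumulative_incidence = mean(.data$max_score == 1),
      .by = dplyr::all_of(c(group_by, "column"))
    ) |>
    dplyr::left_join(catalog[c("item", "column")], by = "column") |>
    dplyr::relocate("item", .after = dplyr::all_of(group_by)) |>
    dplyr::arrange(dplyr::pick(dplyr::all_of(group_by)),
                   dplyr::desc(.data$cumulative_incidence))
}
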