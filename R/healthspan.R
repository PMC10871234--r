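#' Frailty-threshold healthspan endpoint
#'
#' Healthspan is the length of life lived with fewer than `threshold` severe
#' health deficits. The event age is the age at the first assessment with
#' `n_severe >= threshold` (no interpolation between weekly visits; later
#' remission is irrelevant); mice that die without ever crossing are censored
#' at death.
#'
#' @param fgi [fgi_score()] results joined with assessment ages — must carry
#'   `mouse_id`, `n_severe`, and `age_days` (join with the assessment table
#'   if needed).
#' @param mice Mouse table with `lifespan_days`.
#' @param threshold Severe-deficit count defining the end of healthspan.
#' @return Tibble with `mouse_id`, `event_age_days`, `event_observed`
#'   (FALSE = censored at death, `event_age_days` then equals lifespan).
#' @export
compute_healthspan <- function(fgi, mice, threshold = 4) {
  check_columns(fgi, c("mouse_id", "n_severe", "age_days"), "fgi")
  check_columns(mice, c("mouse_id", "lifespan_days"), "mice")
  if (!all(mice$mouse_id %in% fgi$mouse_id)) {
    missing_ids <- setdiff(mice$mouse_id, fgi$mouse_id)
    abort(sprintf("mouse with no assessments: %s", missing_ids[1]))
  }
  events <- fgi |>
    dplyr::filter(!is.na(.data$n_severe)) |>
    dplyr::arrange(.data$mouse_id, .data$age_days) |>
    dplyr::filter(.data$n_severe >= threshold) |>
    dplyr::summarise(event_age_days = dplyr::first(.data$age_days),
                     .by = "mouse_id")
  mice |>
    dplyr::left_join(events, by = "mouse_id") |>
    dplyr::mutate(
      event_observed = !is.na(.data$event_age_days),
      event_age_days = dplyr::coalesce(.data$event_age_days,
                                       .data$lifespan_days)
    ) |>
    dplyr::select("mouse_id", "event_age_days", "event_observed")
}

#' Kaplan-Meier curves for lifespan or healthspan records
#'
#' @param records Tibble with `event_age_days` and `event_observed` (for
#'   lifespan use `lifespan_days` with all events observed), plus any group
#'   column.
#' @param group Optional grouping column name.
#' @param time_col,event_col Column names.
#' @return Tibble of KM step points: group (if any), `time`, `n_risk`,
#'   `n_event`, `surv`, plus attribute `median` per group.
#' @export
km_curve <- function(records, group = NULL, time_col = "event_age_days",
                     event_col = "event_observed") {
  check_columns(records, c(time_col, group, event_col), "records")
  su <- survival::Surv(records[[time_col]],
                       as.numeric(records[[event_col]]))
  fit <- if (is.null(group)) {
    survival::survfit(su ~ 1)
  } else {
    g <- factor(records[[group]])
    survival::survfit(su ~ g)
  }
  s <- summary(fit)
  out <- tibble::tibble(
    time = s$time, n_risk = s$n.risk, n_event = s$n.event, surv = s$surv
  )
  if (!is.null(group)) {
    out$group <- sub("^g=", "", as.character(s$strata))
    out <- dplyr::relocate(out, "group")
  }
  med <- summary(fit)$table
  attr(out, "median") <- if (is.null(dim(med))) unname(med["median"]) else {
    setNames(med[, "median"], sub("^g=", "", rownames(med)))
  }
  out
}

#' Log-rank test across groups
#'
#' @inheritParams km_curve
#' @param group Grouping column name (required, >= 2 groups).
#' @return Tibble with `chisq`, `df`, `p_value`.
#' @export
logrank_test <- function(records, group, time_col = "event_age_days",
                         event_col = "event_observed") {
  check_columns(records, c(time_col, group, event_col), "records")
  g <- factor(records[[group]])
  if (nlevels(g) < 2) abort("need at least 2 groups")
  if (any(table(g) == 0)) abort("empty group")
  fit <- survival::survdiff(
    survival::Surv(records[[time_col]],
                   as.numeric(records[[event_col]])) ~ g
  )
  df <- length(fit$n) - 1
  tibble::tibble(chisq = fit$chisq, df = df,
                 p_value = pchisq(fit$chisq, df, lower.tail = FALSE))
}

#' Group summaries and the maximum-healthspan quantile test
#'
#' Summarises healthspan event ages per group (Kaplan-Meier medians plus
#' naive linear-interpolation quantiles over observed events) and tests the
#' 90th-percentile "maximum healthspan" proportions across groups.
#'
#' @param records [compute_healthspan()] output joined with group columns.
#' @param group Grouping column name.
#' @param q Quantile for the proportions test.
#' @param include_censored Include censored records in the naive quantiles
#'   (KM medians always account for censoring).
#' @return List: `summary` tibble (group, n, n_events, km_median, median,
#'   q1, q3, p90), `quantile_test` tibble.
#' @export
healthspan_summary <- function(records, group, q = 0.9,
                               include_censored = FALSE) {
  check_columns(records, c("event_age_days", "event_observed", group),
                "records")
  km <- km_curve(records, group = group)
  km_med <- attr(km, "median")
  used <- if (include_censored) {
    records
  } else {
    dplyr::filter(records, .data$event_observed)
  }
  summary <- used |>
    dplyr::summarise(
      n_events = dplyr::n(),
      median = quantile_li(.data$event_age_days, 0.5),
      q1 = quantile_li(.data$event_age_days, 0.25),
      q3 = quantile_li(.data$event_age_days, 0.75),
      p90 = quantile_li(.data$event_age_days, 0.9),
      .by = dplyr::all_of(group)
    ) |>
    dplyr::left_join(
      dplyr::count(records, dplyr::pick(dplyr::all_of(group)), name = "n"),
      by = group
    ) |>
    dplyr::mutate(km_median = unname(km_med[as.character(.data[[group]])])) |>
    dplyr::relocate(dplyr::all_of(group), "n", "n_events", "km_median")
  list(
    summary = summary,
    quantile_test = quantile_test(used$event_age_days, used[[group]], q = q)
  )
}
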