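#' Temperature-by-weight product
#'
#' TxW is the product of rectal temperature (Celsius) and body weight
#' (grams). Both decline at the end of life, and a sustained drop of their
#' product is a simple non-invasive flag for terminal decline. A missing
#' input propagates to a missing product; non-positive values are rejected.
#'
#' @param weight_g,temp_C Numeric vectors.
#' @return Numeric vector of products (g*degC).
#' @examples
#' txw(30, 37)  # 1110
#' @export
txw <- function(weight_g, temp_C) {
  if (any(weight_g <= 0 | temp_C <= 0, na.rm = TRUE)) {
    abort("weight and temperature must be positive")
  }
  weight_g * temp_C
}

#' Evaluate the TxW terminal-decline criterion
#'
#' For every assessment date of every mouse, compares the mean TxW in the
#' most recent three weeks against a benchmark mean from the first four
#' weeks of a 13-week look-back interval. A reduction of 10% or more flags
#' terminal decline (`fail`); windows with fewer than `min_obs` observations
#' yield `insufficient`. Window bookkeeping is in days: the benchmark window
#' is `(date - 91, date - 63]` and the recent window `(date - 21, date]`,
#' half-open on the left and closed on the right.
#'
#' @param assessments Assessment table with `mouse_id`, `date`, `weight_g`,
#'   `temp_C` (rows with either missing contribute no TxW observation).
#' @param benchmark_window,recent_window Day offsets (positive, lower bound
#'   exclusive / upper bound inclusive relative to the current date):
#'   defaults `c(91, 63)` and `c(21, 0)`.
#' @param min_obs Minimum observations required in each window.
#' @param drop_pct Percent reduction at or beyond which the flag is `fail`.
#' @return Tibble with `mouse_id`, `date`, `benchmark_mean`, `recent_mean`,
#'   `pct_change`, `flag` in \{pass, fail, insufficient\}.
#' @export
evaluate_txw <- function(assessments,
                         benchmark_window = c(91, 63),
                         recent_window = c(21, 0),
                         min_obs = 2L,
                         drop_pct = 10) {
  check_columns(assessments, c("mouse_id", "date", "weight_g", "temp_C"),
                "assessments")
  dup <- duplicated(assessments[c("mouse_id", "date")])
  if (any(dup)) abort("duplicate (mouse_id, date) in assessments")
  assessments |>
    dplyr::mutate(.txw = txw(.data$weight_g, .data$temp_C)) |>
    dplyr::arrange(.data$mouse_id, .data$date) |>
    dplyr::group_by(.data$mouse_id) |>
    dplyr::group_modify(function(d, key) {
      day <- as.numeric(d$date)
      v <- d$.txw
      n <- nrow(d)
      # window means via cumulative sums over the observed series
      obs <- !is.na(v)
      vo <- v[obs]; do_ <- day[obs]
      cs <- c(0, cumsum(vo))
      win_stats <- function(lo, hi) {
        # observations with day in (current - lo, current - hi]
        i1 <- findInterval(day - lo, do_) + 1L      # first index inside
        i2 <- findInterval(day - hi, do_)           # last index inside
        cnt <- pmax(i2 - i1 + 1L, 0L)
        mean_ <- ifelse(cnt > 0, (cs[i2 + 1L] - cs[i1]) / cnt, NA_real_)
        list(n = cnt, mean = mean_)
      }
      bench <- win_stats(benchmark_window[1], benchmark_window[2])
      recent <- win_stats(recent_window[1], recent_window[2])
      enough <- bench$n >= min_obs & recent$n >= min_obs
      pct <- ifelse(enough,
                    100 * (recent$mean - bench$mean) / bench$mean, NA_real_)
      tibble::tibble(
        date = d$date,
        benchmark_mean = ifelse(enough, bench$mean, NA_real_),
        recent_mean = ifelse(enough, recent$mean, NA_real_),
        pct_change = pct,
        flag = dplyr::case_when(!enough ~ "insufficient",
                                pct <= -drop_pct ~ "fail",
                                TRUE ~ "pass")
      )
    }) |>
    dplyr::ungroup()
}

#' Validate TxW predictions against the 95PLL endpoint
#'
#' Treats `fail` as a positive prediction of imminent terminal decline and
#' computes, per group, the confusion counts against the true 95PLL label
#' plus positive and negative predictive values. PPV is the proportion of
#' positive predictions made at >95% PLL; NPV the proportion of negative
#' predictions made at <=95% PLL. Rows with `insufficient` history are
#' excluded.
#'
#' @param statuses Result of [evaluate_txw()].
#' @param labels Result of [label_assessments()].
#' @param mice Mouse table supplying grouping columns.
#' @param group_by Mouse-level grouping columns (default strain).
#' @return Tibble with group columns, `tp`, `fp`, `tn`, `fn`, `ppv`, `npv`
#'   (NA on empty denominators).
#' @export
validate_txw <- function(statuses, labels, mice, group_by = "strain") {
  joined <- statuses |>
    dplyr::filter(.data$flag != "insufficient") |>
    dplyr::inner_join(labels[c("mouse_id", "date", "is_95pll")],
                      by = c("mouse_id", "date"))
  n_usable <- sum(statuses$flag != "insufficient")
  if (nrow(joined) < n_usable) {
    abort("some TxW statuses have no matching 95PLL label")
  }
  joined <- dplyr::inner_join(
    joined, dplyr::select(mice, dplyr::all_of(c("mouse_id", group_by))),
    by = "mouse_id"
  )
  joined |>
    dplyr::summarise(
      tp = sum(.data$flag == "fail" & .data$is_95pll),
      fp = sum(.data$flag == "fail" & !.data$is_95pll),
      tn = sum(.data$flag == "pass" & !.data$is_95pll),
      fn = sum(.data$flag == "pass" & .data$is_95pll),
      .by = dplyr::all_of(group_by)
    ) |>
    dplyr::mutate(
      ppv = ifelse(.data$tp + .data$fp > 0,
                   .data$tp / (.data$tp + .data$fp), NA_real_),
      npv = ifelse(.data$tn + .data$fn > 0,
                   .data$tn / (.data$tn + .data$fn), NA_real_)
    )
}
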