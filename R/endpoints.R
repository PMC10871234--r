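#' Label assessments with proportion of life lived and the 95PLL endpoint
#'
#' PLL is current age divided by eventual lifespan. The 95PLL event marks an
#' assessment falling strictly within the last 5% of the animal's life
#' (PLL > 0.95); the boundary itself (PLL exactly 0.95) is not an event.
#' Life expectancy is the remaining days to death.
#'
#' @param assessments Assessment table (`mouse_id`, `date`, `age_days`).
#' @param mice Mouse table with `lifespan_days`.
#' @return Tibble with `mouse_id`, `date`, `age_days`, `pll`, `is_95pll`,
#'   `life_expectancy_days`.
#' @examples
#' mice <- tibble::tibble(mouse_id = "m1", lifespan_days = 1000)
#' a <- tibble::tibble(mouse_id = "m1", date = Sys.Date(), age_days = 960)
#' label_assessments(a, mice)
#' @export
label_assessments <- function(assessments, mice) {
  check_columns(assessments, c("mouse_id", "date", "age_days"), "assessments")
  check_columns(mice, c("mouse_id", "lifespan_days"), "mice")
  out <- dplyr::inner_join(
    dplyr::select(assessments, "mouse_id", "date", "age_days"),
    dplyr::select(mice, "mouse_id", "lifespan_days"),
    by = "mouse_id"
  )
  if (nrow(out) < nrow(assessments)) {
    abort("some assessments have no matching mouse with a lifespan")
  }
  if (any(out$age_days > out$lifespan_days)) {
    bad <- which(out$age_days > out$lifespan_days)[1]
    abort(sprintf("assessment age exceeds lifespan for mouse %s",
                  out$mouse_id[bad]))
  }
  out |>
    dplyr::mutate(
      pll = .data$age_days / .data$lifespan_days,
      is_95pll = .data$pll > 0.95,
      life_expectancy_days = .data$lifespan_days - .data$age_days
    ) |>
    dplyr::select("mouse_id", "date", "age_days", "pll", "is_95pll",
                  "life_expectancy_days")
}

#' Summarise lifespan (or any survival time) by group
#'
#' Reports n, median, quartiles, and the 90th percentile ("maximum" lifespan)
#' per group, using the linear-interpolation quantile convention pinned
#' package-wide.
#'
#' @param mice Table with the time column and grouping columns.
#' @param group_by Character vector of grouping columns (empty for overall).
#' @param time_col Column holding the survival times in days.
#' @return Tibble with group columns, `n`, `median`, `q1`, `q3`, `p90` (days).
#' @export
summarize_lifespan <- function(mice, group_by = character(),
                               time_col = "lifespan_days") {
  check_columns(mice, c(time_col, group_by), "mice")
  out <- mice |>
    dplyr::summarise(
      n = dplyr::n(),
      median = quantile_li(.data[[time_col]], 0.5),
      q1 = quantile_li(.data[[time_col]], 0.25),
      q3 = quantile_li(.data[[time_col]], 0.75),
      p90 = quantile_li(.data[[time_col]], 0.9),
      .by = dplyr::all_of(group_by)
    )
  if (any(out$n == 0)) abort("empty group")
  out
}

#' Quantile test of proportions
#'
#' Tests whether groups differ in the proportion of values exceeding the
#' pooled q-th quantile (e.g. q = 0.9 compares "maximum" lifespan across
#' groups). Counts above/below the pooled threshold form a contingency table
#' tested by chi-square, or by Fisher's exact test when any expected cell
#' count is below 5.
#'
#' @param values Numeric vector.
#' @param groups Group labels, same length.
#' @param q Quantile in (0, 1) defining the threshold; default 0.9.
#' @return A tibble with `q`, `threshold`, `method`, `statistic`, `p_value`.
#' @export
quantile_test <- function(values, groups, q = 0.9) {
  stopifnot(length(values) == length(groups), q > 0, q < 1)
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]; groups <- factor(groups[keep])
  if (nlevels(groups) < 2) abort("need at least 2 groups")
  if (length(unique(values)) == 1) {
    abort("degenerate input: all values identical")
  }
  thr <- quantile_li(values, q)
  above <- values > thr
  tab <- table(groups, factor(above, levels = c(FALSE, TRUE)))
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 5)) {
    ft <- fisher.test(tab)
    tibble::tibble(q = q, threshold = thr, method = "fisher",
                   statistic = NA_real_, p_value = ft$p.value)
  } else {
    ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
    tibble::tibble(q = q, threshold = thr, method = "chisq",
                   statistic = unname(ct$statistic), p_value = ct$p.value)
  }
}

#' Median-deviation test of variance homogeneity
#'
#' Brown-Forsythe construction: a one-way ANOVA on absolute deviations from
#' group medians. Robust to non-normality; used to compare lifespan
#' variability across groups.
#'
#' @param values Numeric vector.
#' @param groups Group labels, same length.
#' @return Tibble with `statistic` (F), `df1`, `df2`, `p_value`.
#' @export
median_deviation_variance_test <- function(values, groups) {
  stopifnot(length(values) == length(groups))
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]; groups <- factor(groups[keep])
  if (nlevels(groups) < 2) abort("need at least 2 groups")
  if (any(table(groups) < 2)) abort("every group needs at least 2 values")
  dev <- abs(values - tapply(values, groups, median)[groups])
  fit <- anova(lm(dev ~ groups))
  tibble::tibble(statistic = fit$`F value`[1],
                 df1 = fit$Df[1], df2 = fit$Df[2],
                 p_value = fit$`Pr(>F)`[1])
}

#' Correlations between life expectancy and fragility measures
#'
#' Pearson correlations of remaining life expectancy with each deficit item,
#' the FgI score, the severe-deficit count, chronological age, body weight,
#' and temperature, pooling repeated assessments as independent observations.
#' 95% confidence intervals use the Fisher z transform. Items with zero
#' variance (never-observed deficits) are reported as blank rows (NA
#' coefficients), and the table is sorted by descending absolute correlation.
#'
#' @param assessments Assessment table.
#' @param mice Mouse table with lifespans.
#' @param catalog Deficit catalog.
#' @param fgi Optional precomputed [fgi_score()] result.
#' @param group_by Optional mouse-level grouping columns (e.g. "strain");
#'   correlations are computed within each group, sorted by the first group.
#' @return Tibble with group columns, `variable`, `n`, `r`, `ci_low`,
#'   `ci_high`, `p_value`.
#' @export
deficit_le_correlations <- function(assessments, mice,
                                    catalog = deficit_catalog(),
                                    fgi = NULL,
                                    group_by = "strain") {
  check_catalog(catalog)
  labels <- label_assessments(assessments, mice)
  if (is.null(fgi)) fgi <- fgi_score(assessments, catalog)
  dat <- assessments |>
    dplyr::inner_join(labels[c("mouse_id", "date", "life_expectancy_days")],
                      by = c("mouse_id", "date")) |>
    dplyr::inner_join(fgi[c("mouse_id", "date", "fgi_score", "n_severe")],
                      by = c("mouse_id", "date")) |>
    dplyr::inner_join(dplyr::select(mice,
                                    dplyr::all_of(c("mouse_id", group_by))),
                      by = "mouse_id")
  vars <- c("fgi_score", "n_severe", "age_days", "temp_C", "weight_g",
            catalog$column)
  var_label <- c("FgI Score", "N Deficits", "Age", "Temperature",
                 "Body Weight", catalog$item)
  dat |>
    dplyr::group_by(dplyr::pick(dplyr::all_of(group_by))) |>
    dplyr::group_modify(function(d, key) {
      purrr::map2_dfr(vars, var_label, function(v, lab) {
        x <- d[[v]]; y <- d$life_expectancy_days
        ok <- !is.na(x) & !is.na(y)
        if (sum(ok) < 3 || sd(x[ok]) == 0 || sd(y[ok]) == 0) {
          return(tibble::tibble(variable = lab, n = sum(ok), r = NA_real_,
                                ci_low = NA_real_, ci_high = NA_real_,
                                p_value = NA_real_))
        }
        ct <- cor.test(x[ok], y[ok], method = "pearson")
        tibble::tibble(variable = lab, n = sum(ok), r = unname(ct$estimate),
                       ci_low = ct$conf.int[1], ci_high = ct$conf.int[2],
                       p_value = ct$p.value)
      })
    }) |>
    dplyr::ungroup() |>
    dplyr::arrange(dplyr::pick(dplyr::all_of(group_by)),
                   dplyr::desc(abs(.data$r)))
}
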