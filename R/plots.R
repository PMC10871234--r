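# ggplot2 displays for the main result types.

#' Plot a smoothed PLL trajectory
#'
#' @param object A [pll_trajectory()] result.
#' @param inflection Optionally, the matching [estimate_inflection()] row to
#'   mark with a vertical line.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pll_trajectory <- function(object, inflection = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$pll,
                                            y = .data$fitted)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "Proportion of life lived",
                  y = "Smoothed value") +
    ggplot2::theme_minimal()
  if (!is.null(inflection) && !is.na(inflection$pll_at_inflection[1])) {
    p <- p + ggplot2::geom_vline(xintercept = inflection$pll_at_inflection[1],
                                 linetype = "dashed", colour = "firebrick")
  }
  p
}

#' Plot an ROC curve
#'
#' @param object A [roc_auc()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.roc_result <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step(linewidth = 0.8) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  subtitle = sprintf("AUC = %.3f", object$auc)) +
    ggplot2::theme_minimal()
}

#' Kaplan-Meier plot for lifespan or healthspan
#'
#' @param records Records as for [km_curve()].
#' @param group Optional grouping column.
#' @param time_col,event_col Column names.
#' @param months Convert the time axis from days to months.
#' @return A ggplot of the step survival curves with median markers.
#' @export
plot_km <- function(records, group = NULL, time_col = "event_age_days",
                    event_col = "event_observed", months = TRUE) {
  km <- km_curve(records, group = group, time_col = time_col,
                 event_col = event_col)
  med <- attr(km, "median")
  if (months) {
    km$time <- days_to_months(km$time)
    med <- days_to_months(med)
  }
  aes_ <- if (is.null(group)) {
    ggplot2::aes(x = .data$time, y = .data$surv)
  } else {
    ggplot2::aes(x = .data$time, y = .data$surv, colour = .data$group)
  }
  ggplot2::ggplot(km, aes_) +
    ggplot2::geom_step(linewidth = 0.8) +
    ggplot2::geom_vline(xintercept = unname(med), linetype = "dashed",
                        alpha = 0.4) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = if (months) "Age (months)" else "Age (days)",
                  y = "Survival fraction", colour = group) +
    ggplot2::theme_minimal()
}

#' Mean-absolute-attribution importance plot
#'
#' @param x A [explain_top_member()] result.
#' @param top_n Number of features shown.
#' @return A ggplot bar chart of mean |attribution| per feature.
#' @export
plot_attributions <- function(x, top_n = 15) {
  stopifnot(inherits(x, "shap_result"))
  imp <- sort(colMeans(abs(x$attributions)), decreasing = TRUE)
  d <- tibble::tibble(feature = names(imp), importance = unname(imp)) |>
    head(top_n)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$importance,
                                  y = stats::reorder(.data$feature,
                                                     .data$importance))) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "Mean |attribution|", y = NULL,
                  subtitle = sprintf("member: %s (%s)", x$member,
                                     x$method)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
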