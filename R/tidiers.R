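#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a 95PLL mixed-model fit
#'
#' @param x A `glmm_95pll` object.
#' @param ... Unused.
#' @return One row per fixed effect: `term`, `estimate`, `std_error`,
#'   `statistic`, `p_value`, `conf_low`, `conf_high` (Wald, 95%).
#' @export
tidy.glmm_95pll <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  z <- qnorm(0.975)
  tibble::tibble(
    term = rownames(s),
    estimate = s[, "Estimate"],
    std_error = s[, "Std. Error"],
    statistic = s[, "z value"],
    p_value = s[, "Pr(>|z|)"],
    conf_low = s[, "Estimate"] - z * s[, "Std. Error"],
    conf_high = s[, "Estimate"] + z * s[, "Std. Error"]
  )
}

#' @rdname tidy.glmm_95pll
#' @export
glance.glmm_95pll <- function(x, ...) {
  tibble::tibble(
    n_obs = x$n_obs, n_mice = x$n_mice,
    random_intercept_sd = x$random_intercept_sd,
    converged = x$converged,
    aic = stats::AIC(x$fit), logLik = as.numeric(stats::logLik(x$fit))
  )
}

#' Tidy a stacked ensemble
#'
#' @param x A `pll_ensemble`.
#' @param ... Unused.
#' @return One row per candidate with its learner, recipe, CV AUC and
#'   stacking weight (0 for candidates not retained).
#' @export
tidy.pll_ensemble <- function(x, ...) {
  dplyr::arrange(x$candidate_summary, dplyr::desc(.data$weight))
}

#' @rdname tidy.pll_ensemble
#' @export
glance.pll_ensemble <- function(x, ...) {
  tibble::tibble(
    n_candidates = nrow(x$candidate_summary),
    n_members = length(x$members),
    n_test_mice = length(x$split$test_ids),
    n_train_mice = nrow(x$split$folds),
    meta_intercept = unname(x$stack$intercept),
    seed = x$seed
  )
}
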