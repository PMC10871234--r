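#' Mixed-effects logistic models for 95PLL risk
#'
#' Fits a generalized linear mixed model for the probability that an
#' assessment falls in the last 5% of life (95PLL), with TxW status
#' (pass/fail) — and optionally the FgI score on its natural \[0, 1\] scale —
#' as fixed effects and a per-mouse random intercept. Fitting is by maximum
#' likelihood with the Laplace approximation (via \pkg{lme4}). Rows with
#' insufficient TxW history must be excluded before fitting. Intended to be
#' fit within strain strata.
#'
#' @param rows Tibble with `is_95pll` (logical), `txw_fail` (logical or the
#'   `flag` strings from [evaluate_txw()]), `mouse_id`, and — when
#'   `include_fgi` — `fgi_score`.
#' @param include_fgi Add the FgI score as a second fixed effect.
#' @return An object of class `glmm_95pll`: list with `fit` (the merMod),
#'   `coef` (named fixed-effect vector), `random_intercept_sd`, `converged`,
#'   `n_obs`, `n_mice`, `include_fgi`.
#' @examples
#' \donttest{
#' cohort <- simulate_cohort(cohort_config(n_mice_per_group = 10))
#' rows <- glmm_training_rows(cohort$assessments, cohort$mice)
#' fit <- fit_95pll_glmm(rows)
#' tidy(fit)
#' }
#' @export
fit_95pll_glmm <- function(rows, include_fgi = TRUE) {
  rows <- normalize_glmm_rows(rows, include_fgi)
  if (length(unique(rows$mouse_id)) < 2) abort("need at least 2 mice")
  if (length(unique(rows$is_95pll)) < 2) {
    abort("outcome has a single class; cannot fit")
  }
  form <- if (include_fgi) {
    is_95pll ~ txw_fail + fgi_score + (1 | mouse_id)
  } else {
    is_95pll ~ txw_fail + (1 | mouse_id)
  }
  fit <- suppressMessages(lme4::glmer(form, data = rows, family = binomial()))
  conv <- length(fit@optinfo$conv$lme4$messages) == 0 &&
    fit@optinfo$conv$opt == 0
  fe <- lme4::fixef(fit)
  if (!all(is.finite(fe))) {
    warn("non-finite fixed effects; possible separation")
    conv <- FALSE
  }
  structure(
    list(fit = fit, coef = fe,
         random_intercept_sd =
           sqrt(unname(lme4::VarCorr(fit)$mouse_id[1, 1])),
         converged = conv,
         n_obs = nrow(rows), n_mice = length(unique(rows$mouse_id)),
         include_fgi = include_fgi),
    class = "glmm_95pll"
  )
}

normalize_glmm_rows <- function(rows, include_fgi) {
  need <- c("is_95pll", "mouse_id",
            if (include_fgi) "fgi_score")
  if (!"txw_fail" %in% names(rows) && "flag" %in% names(rows)) {
    rows <- dplyr::filter(rows, .data$flag != "insufficient")
    rows$txw_fail <- rows$flag == "fail"
  }
  check_columns(rows, c(need, "txw_fail"), "rows")
  rows$txw_fail <- as.logical(rows$txw_fail)
  rows[complete.cases(rows[c(need, "txw_fail")]), ]
}

#' Assemble GLMM training rows from assessments
#'
#' Joins TxW statuses, FgI scores and 95PLL labels on (mouse_id, date) and
#' drops rows with insufficient TxW history, producing the input for
#' [fit_95pll_glmm()].
#'
#' @param assessments,mice Cohort tables.
#' @param catalog Deficit catalog.
#' @return Tibble with `mouse_id`, `date`, `txw_fail`, `fgi_score`,
#'   `is_95pll`.
#' @export
glmm_training_rows <- function(assessments, mice,
                               catalog = deficit_catalog()) {
  statuses <- evaluate_txw(assessments)
  labels <- label_assessments(assessments, mice)
  fgi <- fgi_score(assessments, catalog)
  statuses |>
    dplyr::filter(.data$flag != "insufficient") |>
    dplyr::mutate(txw_fail = .data$flag == "fail") |>
    dplyr::inner_join(fgi[c("mouse_id", "date", "fgi_score")],
                      by = c("mouse_id", "date")) |>
    dplyr::inner_join(labels[c("mouse_id", "date", "is_95pll")],
                      by = c("mouse_id", "date")) |>
    dplyr::select("mouse_id", "date", "txw_fail", "fgi_score", "is_95pll")
}

#' Population-level (fixed-effects-only) predicted probabilities
#'
#' Applies the inverse logit to the fixed-effects linear predictor with the
#' random intercept set to zero — the appropriate prediction for mice unseen
#' at training time.
#'
#' @param object A `glmm_95pll` fit.
#' @param rows Tibble with the fixed-effect covariates.
#' @return Numeric vector of probabilities in (0, 1).
#' @export
predict_fixed <- function(object, rows) {
  stopifnot(inherits(object, "glmm_95pll"))
  if (!object$converged) warn("predicting from a non-converged fit")
  rows <- normalize_glmm_rows(rows, object$include_fgi)
  eta <- object$coef[["(Intercept)"]] +
    object$coef[["txw_failTRUE"]] * rows$txw_fail
  if (object$include_fgi) {
    eta <- eta + object$coef[["fgi_score"]] * rows$fgi_score
  }
  plogis(eta)
}

#' @export
print.glmm_95pll <- function(x, ...) {
  cat(sprintf(
    "<glmm_95pll> %s model, %d obs / %d mice, %sconverged\n",
    if (x$include_fgi) "TxW+FgI" else "TxW-only",
    x$n_obs, x$n_mice, if (x$converged) "" else "NOT "))
  print(round(x$coef, 4))
  cat(sprintf("random intercept sd: %.4f\n", x$random_intercept_sd))
  invisible(x)
}
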