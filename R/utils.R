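# Internal helpers shared across modules.

# Days per month used whenever results are reported on the month scale.
DAYS_PER_MONTH <- 30.4375

#' Convert between days and months
#'
#' Reporting in aging studies is conventionally in months while all internal
#' arithmetic in this package is in days. A fixed factor of 30.4375 days per
#' month (the mean Gregorian month) is used everywhere.
#'
#' @param x Numeric vector of days (or months for the inverse).
#' @return Numeric vector.
#' @export
days_to_months <- function(x) x / DAYS_PER_MONTH

#' @rdname days_to_months
#' @export
months_to_days <- function(x) x * DAYS_PER_MONTH

# Deterministically derive a sub-seed from a master seed and a string label.
# Keeps independent randomness sources (cohort simulation, splitting,
# grid sampling, learner fits) reproducible from one master seed while
# guaranteeing the result stays inside R's 32-bit integer range.
derive_seed <- function(seed, key) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(key) * seq_along(utf8ToInt(key)))
  as.integer((abs(as.numeric(seed)) * 48271 + h * 10007) %% 2147483647)
}

# Linear-interpolation quantile (type 7), the single convention pinned for
# medians, IQRs and the 90th-percentile "maximum" lifespan/healthspan.
quantile_li <- function(x, probs) {
  unname(quantile(x, probs = probs, type = 7, na.rm = TRUE))
}

# assert that `df` has the named columns, abort naming the offender
check_columns <- function(df, cols, what = deparse(substitute(df))) {
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0) {
    abort(sprintf("`%s` is missing required column(s): %s",
                  what, paste(miss, collapse = ", ")))
  }
  invisible(df)
}
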