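#' Simulate a longitudinal fragility cohort
#'
#' Generates a mouse-level table, a weekly assessment-level table, and
#' ground-truth labels with the statistical structure a longitudinal frailty
#' study assumes: Gompertz lifespans left-truncated at enrollment, weekly
#' visits from enrollment to natural death, terminal drops in body weight and
#' temperature that follow a logistic ramp in the proportion of life lived
#' (PLL), and per-item ordered-logit deficit trajectories that rise with PLL
#' and accelerate through the same ramp.
#'
#' Deficit trajectories use a per-mouse-per-item latent uniform: the score at
#' a visit is the highest level whose ordered-logit probability exceeds the
#' latent draw. Because the linear predictor is non-decreasing in time, raw
#' trajectories are monotone; transient remission of mild deficits is then
#' overlaid at rate `reversal_prob`. Entire visits are dropped at rate
#' `missing_row_prob` and single items masked at rate `missing_item_prob`
#' (completely at random); items with a positive `start_day` are additionally
#' missing before that study day.
#'
#' @param config A [cohort_config()].
#' @return A list of class `fgi_cohort` with tibbles `mice` (mouse_id, strain,
#'   sex, diet, enrollment_age_days, lifespan_days), `assessments` (mouse_id,
#'   date, age_days, weight_g, temp_C, one column per catalog item), and
#'   `truth` (per-assessment true PLL and 95PLL label plus the per-mouse
#'   decline onset age).
#' @examples
#' cohort <- simulate_cohort(cohort_config(n_mice_per_group = 2, seed = 7))
#' dplyr::count(cohort$mice, strain, diet)
#' @export
simulate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  validate_cohort_config(config)
  withr::with_seed(derive_seed(config$seed, "cohort"), {
    mice <- simulate_mice(config)
    out <- simulate_assessments(mice, config)
    structure(list(mice = mice, assessments = out$assessments,
                   truth = out$truth),
              class = "fgi_cohort")
  })
}

#' @export
print.fgi_cohort <- function(x, ...) {
  cat(sprintf("<fgi_cohort> %d mice, %d assessments\n",
              nrow(x$mice), nrow(x$assessments)))
  print(dplyr::count(x$mice, .data$strain, .data$sex, .data$diet))
  invisible(x)
}

# Group table: B6 crosses sexes at AL; DO is female across diets.
cohort_groups <- function(config) {
  g <- list()
  if ("B6" %in% config$strains) {
    g$b6 <- tidyr::expand_grid(strain = "B6", sex = config$sexes, diet = "AL")
  }
  if ("DO" %in% config$strains) {
    g$do <- tidyr::expand_grid(strain = "DO", sex = "F", diet = config$diets)
  }
  dplyr::bind_rows(g)
}

# Inverse-CDF Gompertz sampler with rejection for left truncation at
# enrollment. h(t) = a * exp(b t) * HR; S(t) = exp(-a HR / b (e^{bt} - 1)).
rgompertz_trunc <- function(n, a, b, hr, t0) {
  a <- rep_len(a, n); b <- rep_len(b, n)
  hr <- rep_len(hr, n); t0 <- rep_len(t0, n)
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need) > 0) {
    u <- runif(length(need))
    t <- log(1 - b[need] * log(u) / (a[need] * hr[need])) / b[need]
    keep <- t > t0[need]
    out[need[keep]] <- t[keep]
    need <- need[!keep]
  }
  out
}

simulate_mice <- function(config) {
  groups <- cohort_groups(config)
  if (nrow(groups) == 0) abort("config selects no cohort groups")
  mice <- groups |>
    dplyr::mutate(n = config$n_mice_per_group) |>
    tidyr::uncount(.data$n)
  mice$enrollment_age_days <- config$enrollment_age_days[mice$strain]
  mice$lifespan_days <- ceiling(rgompertz_trunc(
    nrow(mice),
    a = config$gompertz_a[mice$strain],
    b = config$gompertz_b[mice$strain],
    hr = exp(config$diet_logHR[mice$diet]),
    t0 = mice$enrollment_age_days
  ))
  mice |>
    dplyr::mutate(
      mouse_id = sprintf("%s-%s-%s-%03d", .data$strain, .data$sex, .data$diet,
                         dplyr::row_number()),
      .by = c("strain", "sex", "diet")
    ) |>
    dplyr::select("mouse_id", "strain", "sex", "diet",
                  "enrollment_age_days", "lifespan_days") |>
    tibble::as_tibble()
}

# terminal logistic ramp in PLL
decline_ramp <- function(pll, onset, steepness) {
  plogis(steepness * (pll - onset))
}

simulate_assessments <- function(mice, config) {
  cat30 <- config$catalog
  ip <- config$item_params[match(cat30$column, config$item_params$column), ]
  n_items <- nrow(cat30)

  per_mouse <- purrr::pmap(mice, function(mouse_id, strain, sex, diet,
                                          enrollment_age_days,
                                          lifespan_days) {
    ages <- seq(enrollment_age_days, lifespan_days,
                by = config$assessment_interval_days)
    pll <- ages / lifespan_days
    n_t <- length(ages)

    # between-mouse heterogeneity: individual decline onset, decline
    # magnitude (lognormal multiplier, mean 1), stable frailty level
    onset_m <- min(1, max(0.5, rnorm(1, config$decline_onset_pll,
                                     config$onset_sd_pll)))
    drop_mult <- if (config$terminal_drop_cv > 0) {
      sdlog <- sqrt(log(1 + config$terminal_drop_cv^2))
      exp(rnorm(1, -sdlog^2 / 2, sdlog))
    } else 1
    frailty_m <- rnorm(1, 0, config$mouse_frailty_sd)
    ramp <- decline_ramp(pll, onset_m, config$decline_steepness)

    w0 <- rnorm(1, config$weight_baseline_mean_g, config$weight_baseline_sd_g)
    wander <- if (config$weight_wander_sd_g > 0) {
      cumsum(rnorm(n_t, 0, config$weight_wander_sd_g))
    } else 0
    weight <- w0 +
      config$weight_age_slope_g_per_day * (ages - enrollment_age_days) -
      config$terminal_weight_drop_frac * drop_mult * w0 * ramp +
      wander + rnorm(n_t, 0, config$weight_noise_sd_g)
    # physiological floors: even moribund mice keep positive mass and
    # above-ambient core temperature
    weight <- pmax(weight, 0.25 * w0)
    temp <- pmax(config$temp_baseline_C -
                   config$terminal_temp_drop_C * drop_mult * ramp +
                   rnorm(n_t, 0, config$temp_noise_sd_C), 25)

    # ordered-logit scores via one latent uniform per item (monotone base
    # trajectory), then transient remission of mild scores
    age_yr <- (ages - enrollment_age_days) / 365
    scores <- matrix(0, nrow = n_t, ncol = n_items)
    u <- runif(n_items)
    for (j in seq_len(n_items)) {
      eta <- frailty_m + ip$pll_slope[j] * pll + ip$age_slope[j] * age_yr +
        ip$ramp_gain[j] * ramp
      q_sev <- plogis(eta - ip$c_severe[j])
      s <- ifelse(u[j] < q_sev, 1, 0)
      if (cat30$n_levels[j] == 3L) {
        q_mild <- plogis(eta - ip$c_mild[j])
        s[s == 0 & u[j] < q_mild] <- 0.5
      }
      if (config$reversal_prob > 0) {
        remit <- s == 0.5 & runif(n_t) < config$reversal_prob
        s[remit] <- 0
      }
      scores[, j] <- s
    }

    # item-level MCAR missingness + per-item start day (late-added items)
    if (config$missing_item_prob > 0) {
      scores[matrix(runif(n_t * n_items) < config$missing_item_prob,
                    n_t, n_items)] <- NA_real_
    }
    study_day <- ages - enrollment_age_days
    for (j in which(ip$start_day > 0)) {
      scores[study_day < ip$start_day[j], j] <- NA_real_
    }

    a <- tibble::tibble(
      mouse_id = mouse_id,
      date = config$start_date + study_day,
      age_days = ages,
      weight_g = round(weight, 2),
      temp_C = round(temp, 2)
    )
    a[cat30$column] <- as.data.frame(scores)
    keep <- runif(n_t) >= config$missing_row_prob
    keep[1] <- TRUE  # enrollment visit always conducted
    pll_kept <- pll[keep]
    list(assess = a[keep, ],
         truth = tibble::tibble(mouse_id = mouse_id,
                                date = a$date[keep],
                                pll = pll_kept,
                                is_95pll = pll_kept > 0.95,
                                onset_age_days = onset_m * lifespan_days))
  })

  list(assessments = dplyr::bind_rows(purrr::map(per_mouse, "assess")),
       truth = dplyr::bind_rows(purrr::map(per_mouse, "truth")))
}
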