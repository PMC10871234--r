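#' Configuration for the synthetic cohort generator
#'
#' Bundles every data-generating assumption behind [simulate_cohort()]. The
#' defaults emulate the structure of a two-cohort longitudinal fragility
#' study: inbred C57BL/6J (B6) mice of both sexes enrolled around 24 months
#' fed ad libitum, and Diversity Outbred (DO) females enrolled around 30
#' months across five diet groups (AL, IF1, IF2, CR20, CR40), assessed weekly
#' until natural death. Lifespans follow a Gompertz hazard with per-diet
#' proportional-hazards effects, left-truncated at enrollment. Body weight and
#' temperature carry a terminal drop that follows a logistic ramp in the
#' proportion of life lived (PLL), centered at `decline_onset_pll`; ordinal
#' deficits follow per-item ordered-logit trajectories driven by PLL, age, and
#' the same terminal ramp.
#'
#' @param n_mice_per_group Mice per strain-by-sex-by-diet group.
#' @param strains,diets,sexes Character vectors selecting which groups exist.
#'   B6 mice are always AL-fed (both sexes); DO mice are always female (all
#'   requested diets).
#' @param enrollment_age_days Named vector (B6, DO) of enrollment ages in days.
#' @param gompertz_a,gompertz_b Named vectors (B6, DO): baseline Gompertz
#'   hazard scale (per day) and shape (per day).
#' @param diet_logHR Named vector of per-diet log hazard ratios (AL = 0).
#' @param decline_onset_pll Center of the terminal-decline logistic ramp on
#'   the PLL scale, in (0, 1].
#' @param decline_steepness Slope of the terminal ramp (unitless; larger is
#'   sharper). The ramp at PLL p is `plogis(decline_steepness * (p - onset))`.
#' @param onset_sd_pll Between-mouse SD of the individual decline onset
#'   around `decline_onset_pll` (real animals do not share one onset).
#' @param terminal_drop_cv Coefficient of variation of a per-mouse lognormal
#'   multiplier (mean 1) on the terminal weight and temperature drops; some
#'   animals decline steeply, others barely.
#' @param mouse_frailty_sd SD of a per-mouse intercept added to every item's
#'   latent severity (stable between-animal frailty differences).
#' @param weight_wander_sd_g Per-visit SD of a slow random-walk drift in body
#'   weight, independent of the terminal drop.
#' @param weight_baseline_mean_g,weight_baseline_sd_g Per-mouse baseline
#'   weight distribution (grams).
#' @param weight_age_slope_g_per_day Mild linear weight trend with age.
#' @param temp_baseline_C Baseline rectal temperature (Celsius).
#' @param terminal_weight_drop_frac Fraction of baseline weight lost over the
#'   full terminal ramp.
#' @param terminal_temp_drop_C Temperature drop (Celsius) over the full ramp.
#' @param weight_noise_sd_g,temp_noise_sd_C Observation noise SDs.
#' @param item_params Per-item ordered-logit parameters; see
#'   [default_item_params()].
#' @param reversal_prob Probability that a mild (non-severe) deficit is
#'   observed as remitted at a given visit.
#' @param missing_row_prob Probability an entire scheduled assessment is
#'   skipped.
#' @param missing_item_prob Probability an individual item score is missing
#'   at an otherwise conducted visit.
#' @param assessment_interval_days Days between scheduled assessments.
#' @param start_date Calendar date of the first assessment (arbitrary epoch;
#'   only date differences matter downstream).
#' @param catalog Deficit catalog, see [deficit_catalog()].
#' @param seed Integer seed; the same config and seed reproduce the cohort
#'   byte-identically.
#' @return A list with class `cohort_config`.
#' @seealso [simulate_cohort()], [default_item_params()]
#' @export
cohort_config <- function(n_mice_per_group = 20,
                          strains = c("B6", "DO"),
                          diets = c("AL", "IF1", "IF2", "CR20", "CR40"),
                          sexes = c("F", "M"),
                          enrollment_age_days = c(B6 = 730, DO = 913),
                          gompertz_a = c(B6 = 3.2e-5, DO = 9.6e-5),
                          gompertz_b = c(B6 = 0.006, DO = 0.004),
                          diet_logHR = c(AL = 0, IF1 = -0.3, IF2 = -0.6,
                                         CR20 = -0.9, CR40 = -1.3),
                          decline_onset_pll = 0.95,
                          decline_steepness = 150,
                          onset_sd_pll = 0.02,
                          terminal_drop_cv = 0.5,
                          mouse_frailty_sd = 0.5,
                          weight_wander_sd_g = 0.4,
                          weight_baseline_mean_g = 30,
                          weight_baseline_sd_g = 3,
                          weight_age_slope_g_per_day = -0.01,
                          temp_baseline_C = 37.2,
                          terminal_weight_drop_frac = 0.2,
                          terminal_temp_drop_C = 2,
                          weight_noise_sd_g = 0.8,
                          temp_noise_sd_C = 0.3,
                          item_params = default_item_params(catalog),
                          reversal_prob = 0.05,
                          missing_row_prob = 0.01,
                          missing_item_prob = 0.002,
                          assessment_interval_days = 7,
                          start_date = as.Date("2019-09-01"),
                          catalog = deficit_catalog(),
                          seed = 1L) {
  cfg <- list(
    n_mice_per_group = n_mice_per_group, strains = strains, diets = diets,
    sexes = sexes, enrollment_age_days = enrollment_age_days,
    gompertz_a = gompertz_a, gompertz_b = gompertz_b, diet_logHR = diet_logHR,
    decline_onset_pll = decline_onset_pll,
    decline_steepness = decline_steepness,
    onset_sd_pll = onset_sd_pll,
    terminal_drop_cv = terminal_drop_cv,
    mouse_frailty_sd = mouse_frailty_sd,
    weight_wander_sd_g = weight_wander_sd_g,
    weight_baseline_mean_g = weight_baseline_mean_g,
    weight_baseline_sd_g = weight_baseline_sd_g,
    weight_age_slope_g_per_day = weight_age_slope_g_per_day,
    temp_baseline_C = temp_baseline_C,
    terminal_weight_drop_frac = terminal_weight_drop_frac,
    terminal_temp_drop_C = terminal_temp_drop_C,
    weight_noise_sd_g = weight_noise_sd_g, temp_noise_sd_C = temp_noise_sd_C,
    item_params = item_params, reversal_prob = reversal_prob,
    missing_row_prob = missing_row_prob,
    missing_item_prob = missing_item_prob,
    assessment_interval_days = assessment_interval_days,
    start_date = as.Date(start_date), catalog = catalog,
    seed = as.integer(seed)
  )
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
}

validate_cohort_config <- function(cfg) {
  check_catalog(cfg$catalog)
  if (any(cfg$n_mice_per_group <= 0)) abort("n_mice_per_group must be positive")
  if (!all(cfg$strains %in% c("B6", "DO"))) abort("strains must be B6 and/or DO")
  if (!all(cfg$diets %in% c("AL", "IF1", "IF2", "CR20", "CR40"))) {
    abort("unknown diet group")
  }
  if (cfg$decline_onset_pll <= 0 || cfg$decline_onset_pll > 1) {
    abort("decline_onset_pll must lie in (0, 1]")
  }
  probs <- c(cfg$reversal_prob, cfg$missing_row_prob, cfg$missing_item_prob)
  if (any(probs < 0 | probs > 1)) abort("probabilities must lie in [0, 1]")
  if (any(cfg$enrollment_age_days[cfg$strains] <= 0)) {
    abort("enrollment_age_days must be positive")
  }
  ip <- cfg$item_params
  check_columns(ip, c("column", "c_mild", "c_severe", "pll_slope",
                      "age_slope", "ramp_gain", "start_day"), "item_params")
  if (!setequal(ip$column, cfg$catalog$column) ||
      nrow(ip) != nrow(cfg$catalog)) {
    abort("item_params must cover exactly the 30 catalog items")
  }
  cfg
}

#' Default per-item trajectory parameters
#'
#' Each deficit follows an ordered-logit model: at PLL p and age a (days since
#' enrollment), the latent severity is
#' `eta = pll_slope * p + age_slope * a / 365 + ramp_gain * ramp(p)`, where
#' `ramp` is the terminal logistic ramp shared with weight and temperature.
#' The probability of at least a mild score is `plogis(eta - c_mild)` and of a
#' severe score `plogis(eta - c_severe)`; a per-mouse-item latent uniform
#' makes trajectories monotone unless remission is simulated. Items fall into
#' four incidence tiers: near-universal signs of aging (piloerection,
#' kyphosis, coat condition, hunched posture), a common middle tier, a rare
#' tier, and two items that are never observed (nasal discharge and
#' vaginal/uterine prolapse), emulating floor effects seen in real cohorts
#' and exercising downstream zero-variance handling. Head piloerection and
#' thoracic mass default to a study-day 90 start (items added to the index
#' after follow-up began), giving structured early missingness.
#'
#' @param catalog Deficit catalog.
#' @return Tibble with columns `column`, `c_mild`, `c_severe`, `pll_slope`,
#'   `age_slope`, `ramp_gain`, `start_day`.
#' @export
default_item_params <- function(catalog = deficit_catalog()) {
  high <- c("piloerection", "kyphosis", "coat_condition", "hunched")
  rare <- c("peri_retro_orbital_swelling", "malocclusions", "diarrhea",
            "paralysis", "rectal_prolapse")
  never <- c("nasal_discharge", "vaginal_uterine_prolapse")
  late_start <- c("head_piloerection", "thoracic_mass")

  tier <- dplyr::case_when(
    catalog$column %in% never ~ "never",
    catalog$column %in% high ~ "high",
    catalog$column %in% rare ~ "rare",
    TRUE ~ "mid"
  )
  tibble::tibble(
    column = catalog$column,
    c_mild = c(high = 2.2, mid = 3.5, rare = 5.5, never = Inf)[tier],
    c_severe = c(high = 4.0, mid = 6.5, rare = 7.5, never = Inf)[tier],
    pll_slope = 3,
    age_slope = 0,
    ramp_gain = 2.5,
    start_day = ifelse(catalog$column %in% late_start, 90, 0)
  )
}
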