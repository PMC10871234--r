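#' Read and write cohort configurations as YAML
#'
#' The full [cohort_config()] — including the deficit catalog and per-item
#' trajectory parameters — round-trips through a structured YAML file, so a
#' simulation is fully described by one text document plus a seed. Scalar
#' fields map to keys, named vectors to mappings, and the catalog and
#' `item_params` tables to per-item records. A `schema_version` key marks
#' the layout.
#'
#' @param config A `cohort_config`.
#' @param path File path.
#' @return `write_cohort_config()` returns `path` invisibly;
#'   `read_cohort_config()` returns a validated `cohort_config`.
#' @export
write_cohort_config <- function(config, path) {
  stopifnot(inherits(config, "cohort_config"))
  x <- unclass(config)
  x$start_date <- format(x$start_date)
  x$catalog <- lapply(seq_len(nrow(config$catalog)), function(i) {
    as.list(config$catalog[i, ])
  })
  ip <- config$item_params
  ip$c_mild <- ifelse(is.infinite(ip$c_mild), ".inf", ip$c_mild)
  ip$c_severe <- ifelse(is.infinite(ip$c_severe), ".inf", ip$c_severe)
  x$item_params <- lapply(seq_len(nrow(ip)), function(i) as.list(ip[i, ]))
  for (nm in names(x)) {
    if (is.numeric(x[[nm]]) && !is.null(names(x[[nm]]))) {
      x[[nm]] <- as.list(x[[nm]])
    }
  }
  yaml::write_yaml(c(list(schema_version = 1L), x), path)
  invisible(path)
}

#' @rdname write_cohort_config
#' @export
read_cohort_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  x <- yaml::read_yaml(path)
  if (is.null(x$schema_version) || x$schema_version != 1L) {
    abort("unsupported or missing config schema_version (expected 1)")
  }
  x$schema_version <- NULL
  catalog <- dplyr::bind_rows(lapply(x$catalog, tibble::as_tibble)) |>
    dplyr::mutate(n_levels = as.integer(.data$n_levels))
  num_inf <- function(v) {
    as.numeric(ifelse(v %in% c(".inf", "Inf"), Inf, v))
  }
  ip <- dplyr::bind_rows(lapply(x$item_params, tibble::as_tibble)) |>
    dplyr::mutate(c_mild = num_inf(.data$c_mild),
                  c_severe = num_inf(.data$c_severe))
  named <- function(v) unlist(v)
  cohort_config(
    n_mice_per_group = x$n_mice_per_group,
    strains = unlist(x$strains), diets = unlist(x$diets),
    sexes = unlist(x$sexes),
    enrollment_age_days = named(x$enrollment_age_days),
    gompertz_a = named(x$gompertz_a), gompertz_b = named(x$gompertz_b),
    diet_logHR = named(x$diet_logHR),
    decline_onset_pll = x$decline_onset_pll,
    decline_steepness = x$decline_steepness,
    onset_sd_pll = x$onset_sd_pll,
    terminal_drop_cv = x$terminal_drop_cv,
    mouse_frailty_sd = x$mouse_frailty_sd,
    weight_wander_sd_g = x$weight_wander_sd_g,
    weight_baseline_mean_g = x$weight_baseline_mean_g,
    weight_baseline_sd_g = x$weight_baseline_sd_g,
    weight_age_slope_g_per_day = x$weight_age_slope_g_per_day,
    temp_baseline_C = x$temp_baseline_C,
    terminal_weight_drop_frac = x$terminal_weight_drop_frac,
    terminal_temp_drop_C = x$terminal_temp_drop_C,
    weight_noise_sd_g = x$weight_noise_sd_g,
    temp_noise_sd_C = x$temp_noise_sd_C,
    item_params = ip, reversal_prob = x$reversal_prob,
    missing_row_prob = x$missing_row_prob,
    missing_item_prob = x$missing_item_prob,
    assessment_interval_days = x$assessment_interval_days,
    start_date = as.Date(x$start_date),
    catalog = catalog, seed = x$seed
  )
}
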