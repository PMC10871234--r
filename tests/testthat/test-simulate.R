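test_that("identical config and seed reproduce the cohort exactly", {
  cfg <- cohort_config(n_mice_per_group = 3, seed = 11)
  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(cfg)
  expect_identical(c1$mice, c2$mice)
  expect_identical(c1$assessments, c2$assessments)
  expect_identical(c1$truth, c2$truth)
  c3 <- simulate_cohort(cohort_config(n_mice_per_group = 3, seed = 12))
  expect_false(identical(c1$mice, c3$mice))
})

test_that("weekly schedule yields floor((lifespan - enrollment)/7) + 1 visits", {
  cfg <- cohort_config(n_mice_per_group = 4, missing_row_prob = 0, seed = 5)
  co <- simulate_cohort(cfg)
  counts <- dplyr::count(co$assessments, mouse_id)
  expected <- with(co$mice,
                   floor((lifespan_days - enrollment_age_days) / 7) + 1)
  expect_equal(counts$n[match(co$mice$mouse_id, counts$mouse_id)],
               unname(expected))
})

test_that("terminal weight drop is visible per mouse in a noise-free cohort", {
  cfg <- cohort_config(
    n_mice_per_group = 6, strains = "DO",
    enrollment_age_days = c(B6 = 730, DO = 300),  # early enrollment: PLL < 0.5 observed
    terminal_weight_drop_frac = 0.2, terminal_drop_cv = 0,
    weight_noise_sd_g = 0, weight_wander_sd_g = 0, temp_noise_sd_C = 0,
    missing_row_prob = 0, seed = 21
  )
  co <- simulate_cohort(cfg)
  labelled <- label_assessments(co$assessments, co$mice)
  d <- dplyr::inner_join(co$assessments, labelled,
                         by = c("mouse_id", "date", "age_days"))
  cmp <- d |>
    dplyr::summarise(
      early = mean(weight_g[pll < 0.5]),
      late = mean(weight_g[pll > 0.99]),
      .by = mouse_id
    ) |>
    dplyr::filter(!is.nan(early) & !is.nan(late))
  expect_gt(nrow(cmp), 0)
  expect_true(all(cmp$late < cmp$early))
})

test_that("deficit trajectories are monotone when remission is off", {
  cfg <- cohort_config(n_mice_per_group = 4, reversal_prob = 0,
                       missing_row_prob = 0, missing_item_prob = 0, seed = 31)
  co <- simulate_cohort(cfg)
  items <- cfg$catalog$column
  non_decreasing <- co$assessments |>
    dplyr::arrange(mouse_id, date) |>
    dplyr::group_by(mouse_id) |>
    dplyr::summarise(dplyr::across(
      dplyr::all_of(items),
      ~ all(diff(stats::na.omit(.x)) >= 0)
    ))
  expect_true(all(as.matrix(non_decreasing[items])))
})

test_that("generated ages, PLL and truth labels respect their invariants", {
  co <- test_cohort()
  joined <- dplyr::inner_join(co$assessments, co$mice, by = "mouse_id")
  expect_true(all(joined$age_days <= joined$lifespan_days))
  expect_true(all(co$truth$pll > 0 & co$truth$pll <= 1))
  expect_equal(co$truth$is_95pll, co$truth$pll > 0.95)
  onset <- dplyr::distinct(co$truth, mouse_id, onset_age_days)
  m <- dplyr::inner_join(onset, co$mice, by = "mouse_id")
  expect_true(all(m$onset_age_days < m$lifespan_days + 1e-9))
})

test_that("late-added items are missing before their start day", {
  co <- test_cohort()
  early <- dplyr::filter(co$assessments,
                         as.numeric(date - min(date)) < 90, .by = mouse_id)
  expect_true(all(is.na(early$head_piloerection)))
  expect_true(all(is.na(early$thoracic_mass)))
})

test_that("invalid configurations are rejected", {
  expect_error(cohort_config(n_mice_per_group = 0), "positive")
  expect_error(cohort_config(decline_onset_pll = 1.2), "0, 1")
  expect_error(cohort_config(missing_row_prob = 1.5), "0, 1")
  bad_items <- default_item_params()[1:10, ]
  expect_error(cohort_config(item_params = bad_items), "30 catalog items")
})

test_that("simulated lifespans match the closed-form truncated Gompertz median", {
  cfg <- cohort_config(n_mice_per_group = 1000, strains = "DO", diets = "AL",
                       seed = 77)
  mice <- withr::with_seed(1, fragility:::simulate_mice(cfg))
  a <- cfg$gompertz_a[["DO"]]; b <- cfg$gompertz_b[["DO"]]
  t0 <- cfg$enrollment_age_days[["DO"]]
  # S(t | T > t0) = 0.5  =>  t_med = log(exp(b t0) + b log 2 / a) / b
  t_med <- log(exp(b * t0) + b * log(2) / a) / b
  # SE of the sample median from the conditional density at the median
  dens <- a * exp(b * t_med) * 0.5
  se <- 1 / (2 * dens * sqrt(nrow(mice)))
  km <- summary(survival::survfit(
    survival::Surv(mice$lifespan_days, rep(1, nrow(mice))) ~ 1
  ))$table[["median"]]
  expect_lt(abs(km - t_med), 2 * se + 1)  # +1 day for ceiling() rounding
})

test_that("mean FgI rises monotonically across PLL deciles", {
  co <- cached("cohort_decile", simulate_cohort(
    cohort_config(n_mice_per_group = 40, strains = "DO", seed = 55)
  ))
  expect_gte(nrow(co$mice), 200)
  f <- fgi_score(co$assessments)
  l <- label_assessments(co$assessments, co$mice)
  d <- dplyr::inner_join(f, l, by = c("mouse_id", "date"))
  d$decile <- dplyr::ntile(d$pll, 10)
  by_dec <- dplyr::summarise(d, m = mean(fgi_score, na.rm = TRUE),
                             .by = decile)
  rho <- cor(by_dec$decile, by_dec$m, method = "spearman")
  expect_gt(rho, 0.9)
})
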