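# Shared fixtures, built in code and cached for the duration of the run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# small default-condition cohort shared by many files
test_cohort <- function() {
  cached("cohort_small", simulate_cohort(cohort_config(n_mice_per_group = 6,
                                                       seed = 101)))
}

# DO-only cohort for ML tests (40 mice)
test_cohort_do <- function() {
  cached("cohort_do", simulate_cohort(cohort_config(
    n_mice_per_group = 8, strains = "DO", seed = 202
  )))
}

# a tiny trained ensemble reused across ensemble/explain/tidier tests
test_ensemble <- function() {
  cached("ensemble_small", {
    co <- test_cohort_do()
    suppressWarnings(train_95pll_ensemble(
      co$assessments, co$mice,
      learners = c("rlr", "xgb"), recipes = c("M0", "M2"),
      grid_size = 2, seed = 7
    ))
  })
}

# blank wide assessment table with all catalog items zero
blank_assessments <- function(n, catalog = deficit_catalog(),
                              mouse_id = sprintf("m%03d", seq_len(n)),
                              age_days = seq(700, length.out = n, by = 7)) {
  a <- tibble::tibble(
    mouse_id = mouse_id,
    date = as.Date("2020-01-01") + seq_len(n) - 1,
    age_days = age_days,
    weight_g = 30,
    temp_C = 37
  )
  for (cl in catalog$column) a[[cl]] <- 0
  a
}
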