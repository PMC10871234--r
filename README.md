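# fragility

Frailty-based lifespan and healthspan endpoints for longitudinal mouse
aging studies.

Aging studies in mice use natural lifespan as their primary outcome, which
makes them slow and motivates noninvasive proxies for imminent terminal
decline. This package implements, as a tested and reusable R pipeline, the
analysis stack such studies need:

* **Fragility Index (FgI) scoring** — the mean level across 30 ordinal
  health deficits (0 absent, 0.5 mild, 1 severe), giving a per-assessment
  score in [0, 1], plus severe-deficit counts and per-item cumulative
  incidence.
* **TxW terminal-decline criterion** — a sustained ≥10% drop of the mean
  temperature × weight product (recent ≤3 weeks vs. a benchmark 9–13 weeks
  back) flags terminal decline; validated by PPV/NPV against the true
  endpoint.
* **PLL endpoints** — proportion of life lived (age/lifespan) and the
  95PLL event: an assessment in the last 5% of an animal's life
  (PLL > 0.95).
* **95PLL classifiers** — logistic mixed models (TxW-only and TxW + FgI,
  per-mouse random intercept, fixed-effects-only held-out prediction) and
  a stacked machine-learning ensemble (RLR/RF/SVM/XGB × four nested
  feature recipes, grouped 5-fold CV with racing, L1 non-negative
  stacking, threshold sweep, Shapley attribution).
* **Healthspan** — length of life with fewer than four severe deficits,
  censored at death, with Kaplan–Meier curves, log-rank tests, and
  quantile tests of "maximum" (90th-percentile) lifespan/healthspan.
* **A synthetic cohort generator** — Gompertz mortality with per-diet
  hazard ratios, weekly assessments, logistic terminal-decline ramps in
  weight/temperature, ordered-logit deficit trajectories, between-mouse
  heterogeneity, and ground-truth labels — so the full pipeline is
  testable without animal data.

All user-facing functions take data frames and return tibbles, so stages
chain with the pipe; fitted objects have `tidy()`/`glance()` methods and
results have `autoplot()`/`plot_*()` displays.

## Worked example

```r
library(fragility)
library(dplyr)

cohort <- simulate_cohort(cohort_config(n_mice_per_group = 20, seed = 1))
cohort
#> <fgi_cohort> 140 mice, 4679 assessments

# score and label
fgi <- fgi_score(cohort$assessments)
labels <- label_assessments(cohort$assessments, cohort$mice)
summary(fgi$fgi_score)
#>    Min. 1st Qu.  Median    Mean 3rd Qu.    Max.
#>  0.0000  0.1071  0.1786  0.2215  0.2857  0.7167

# lifespan summaries (days -> months)
summarize_lifespan(filter(cohort$mice, strain == "DO")) |>
  mutate(across(median:p90, days_to_months))
#> # A tibble: 1 x 5
#>       n median    q1    q3   p90
#>   <int>  <dbl> <dbl> <dbl> <dbl>
#> 1   100   36.9  34.4  41.2  44.8

# TxW criterion vs. the 95PLL endpoint
statuses <- evaluate_txw(cohort$assessments)
validate_txw(statuses, labels, cohort$mice)
#> # A tibble: 2 x 7
#>   strain    tp    fp    tn    fn   ppv   npv
#>   <chr>  <int> <int> <int> <int> <dbl> <dbl>
#> 1 B6       167    54   518    54 0.756 0.906
#> 2 DO       549   202  1640   174 0.731 0.904

# FgI trajectory inflection on the PLL scale
d <- inner_join(fgi, labels, by = c("mouse_id", "date"))
estimate_inflection(pll_trajectory(d))
#> # A tibble: 1 x 3
#>   pll_at_inflection curvature pll_max_curvature
#>               <dbl>     <dbl>             <dbl>
#> 1             0.958   0.00360              0.94
```

The TxW flag has high negative but lower positive predictive value, the
FgI trajectory shows its inflection near 0.95 PLL — the generator's
planted decline onset — and a stacked ensemble trained on the same cohort
(`train_95pll_ensemble()`) outranks both mixed models on held-out mice.

`run_pipeline(cohort_config(...), out_dir)` executes every stage and
writes all CSV/JSON outputs plus a manifest with config hash and file
checksums; identical config and seed reproduce the outputs byte-for-byte.
Configurations round-trip through YAML
(`write_cohort_config()`/`read_cohort_config()`), so a simulation is fully
described by one text file plus a seed.

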