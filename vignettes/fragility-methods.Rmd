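---
title: "Frailty-based endpoints for mouse aging studies: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Frailty-based endpoints for mouse aging studies: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fragility)
library(dplyr)
```

## Scope

`fragility` implements an analysis pipeline for longitudinal frailty
phenotyping in aging mouse cohorts: Fragility Index (FgI) scoring of 30
ordinal health deficits, the temperature-by-weight (TxW) moving-average
criterion for imminent terminal decline, proportion-of-life-lived (PLL)
endpoints, mixed-effects and stacked-ensemble classifiers of the 95PLL
event (the last 5% of life), and a frailty-threshold healthspan endpoint.
Because raw data from real cohorts of this design are generally not public,
the package is organised around a synthetic-cohort generator whose output
has the statistical structure the analyses assume; every stage is exercised
and tested against that generator.

## The synthetic cohort

### Study design emulated

Two cohorts are generated by default, mirroring a two-population
longitudinal fragility study: inbred C57BL/6J (B6) mice of both sexes
enrolled at 24 months and fed ad libitum, and Diversity Outbred (DO)
females enrolled at 30 months across five diet groups (AL, IF1, IF2, CR20,
CR40). Assessments are weekly from enrollment until natural death: body
weight (g), rectal temperature (°C), and the 30 ordinal deficits.

### Mortality

Lifespans are drawn from a Gompertz hazard, the standard parametric model
for adult murine mortality,

$$h(t) = a\, e^{b t}\, e^{\beta_{\text{diet}}},$$

left-truncated at the enrollment age by rejection sampling (simple and
adequate at desk scale). The baseline scale $a$ and per-diet log hazard
ratios are calibrated so that conditional median lifespans land near the
benchmarks the package targets: about 34.6 months in the shortest-lived
(AL) and 40.8 months in the longest-lived (CR40) DO group, roughly 37
months overall, and about 29.3 months for B6 — values typical of aged
cohorts enrolled at these ages. The shape parameters ($b$ = 0.004/day for
DO, 0.006/day for B6) correspond to mortality-rate doubling times of about
5.8 and 3.9 months.

### Terminal decline

End-of-life decline is modelled as a logistic ramp on the PLL scale,
$r(p) = \mathrm{logis}(k (p - p_0))$, with onset $p_0 = 0.95$ and
steepness $k = 150$ by default. The steepness was chosen so the 10–90%
width of the ramp is about 0.03 PLL — i.e. terminal decline unfolding over
the final two to three weeks of a roughly three-year life, the time scale
on which sustained weight and temperature drops are reported in aged mice.
A smooth ramp rather than a hard changepoint gives the inflection
estimator a well-defined target.

Weight and temperature carry the ramp directly: weight falls by a fraction
(default 20%) of the per-mouse baseline and temperature by 2&nbsp;°C over the
full ramp, plus observation noise (0.8 g, 0.3 °C).

### Between-animal heterogeneity

Real cohorts do not share a single decline trajectory, and a generator
without individual heterogeneity makes every predictor look nearly perfect.
Four sources are therefore built in, each config-exposed:

* **onset jitter** — each mouse's ramp center is drawn around $p_0$
  (SD 0.02 PLL);
* **decline magnitude** — a per-mouse lognormal multiplier (mean 1,
  CV 0.5) scales both the weight and temperature drops, so some animals
  decline steeply and some barely;
* **stable frailty level** — a per-mouse intercept (SD 0.5 logits) shifts
  every deficit's latent severity;
* **weight wander** — a slow random walk (0.4 g/visit SD) superimposed on
  body weight, independent of terminal decline.

With these defaults the TxW criterion and the FgI-based classifiers are
informative but imperfect, which is the regime the downstream comparisons
are designed for.

### Deficit trajectories

No quantitative per-item trajectory model is available from published
cohort descriptions, so the generator adopts an ordered-logit form,
flagged as a modelling choice: item $j$ has latent severity
$\eta_j(p) = \alpha_m + s_j p + g_j r(p) + c_j \cdot \text{age}$, and the
probabilities of at-least-mild and severe scores are
$\mathrm{logis}(\eta_j - \kappa^{\text{mild}}_j)$ and
$\mathrm{logis}(\eta_j - \kappa^{\text{sev}}_j)$. A single latent uniform
per mouse-item converts these into scores, which makes trajectories
monotone whenever $\eta$ is non-decreasing and reproduces the marginal
ordered-logit prevalences exactly; transient remission of mild scores is
overlaid at a configurable rate (default 0.05/visit). Items fall into four
incidence tiers (near-universal, common, rare, never observed); the two
never-observed items emulate floor effects seen in real data and exercise
the zero-variance filter downstream. Default cutpoints were calibrated so
that cohort-level summaries match the package's targets: FgI scores
spanning roughly 0.02–0.6, and a median per-mouse maximum of about 9
severe deficits. Two items (head piloerection, thoracic mass) default to a
study-day-90 start, emulating items added to an index after follow-up
began.

### What the generator does not emulate

Specific pathologies, cause-of-death structure, technician effects,
informative missingness, and fighting-related censoring are all absent;
missingness is completely at random apart from item start dates. Passing
tests on this generator therefore demonstrate correctness of the
*methods* under a plausible data-generating process, not performance
claims about real cohorts — on real data every classifier metric is
expected to be substantially lower.

## FgI scoring

The FgI score of an assessment is the mean deficit level across observed
items (range 0–1). Missing items are dropped from the denominator — no
imputation — so scores remain defined while late-added items were not yet
collected. "Severe" is a score exactly at the item's maximum (1 for both
two- and three-level items), and the severe-deficit count `n_severe` feeds
the healthspan endpoint. The four-level dermatitis assessment collapses to
three levels via 0→0, 1→0.5, 2→0.5, 3→1; any monotone surjection onto
\{0, 0.5, 1\} would serve, and this one is pinned for reproducibility.
Which items are two-level is not fixed by any published list and is
config-exposed, with a five-item default.

## TxW criterion

TxW is weight × temperature. For each assessment the mean over a recent
window is compared with a benchmark window from the start of a 13-week
look-back: windows are pinned in days as (date−91, date−63] and
(date−21, date], half-open on the left, requiring at least 2 observations
each; a drop of 10% or more (inclusive boundary) flags terminal decline.
Day arithmetic avoids week-boundary ambiguity under missed visits; the
inclusive boundary affects a measure-zero set under noise. Validation
against the 95PLL label reports PPV and NPV per stratum, with
insufficient-history rows excluded.

## Endpoints and group statistics

PLL is age divided by eventual lifespan; the 95PLL event is strict
(`pll > 0.95`). One quantile convention — linear interpolation, R type 7 —
is used for every median, IQR and 90th-percentile ("maximum" lifespan)
statistic. The quantile test of proportions thresholds at the pooled
q-th quantile and tests the per-group above-threshold counts by chi-square
(Fisher's exact test when any expected cell is below 5). Variance
homogeneity uses the Brown–Forsythe construction: one-way ANOVA on
absolute deviations from group medians. Correlations with life expectancy
pool repeated assessments as independent rows (as is conventional for
descriptive item screens; a clustered alternative would shrink the
confidence intervals' coverage error but is out of scope), with Fisher-z
intervals and blank rows for zero-variance items.

## Trajectories and inflection

FgI-versus-PLL curves are smoothed by local polynomial (loess) regression,
span 0.2, evaluated on a 0.005 PLL grid. The inflection search runs on
PLL ∈ [0.6, 1.0], the conventional display range for terminal
trajectories. For a sigmoidal ramp the discrete-curvature *maximum* sits
systematically early — at $p_0 - 1.32/k_{\text{eff}}$ for a logistic with
effective steepness $k_{\text{eff}}$, which smoothing and onset jitter
reduce well below the nominal $k$ — so the estimator instead reports the
midpoint of the curvature maximum and the following curvature minimum,
which is unbiased for any symmetric ramp and falls back to the raw peak
when no deceleration point exists. Curves whose maximum curvature is below
a small tolerance (1e-4 per grid-step², e.g. straight lines) yield no
inflection. On 300-mouse cohorts this recovers planted onsets of 0.95 and
0.80 to within 0.02 PLL.

## 95PLL classifiers

### Mixed models

Within strain strata, `is_95pll` is modelled by logistic mixed regression
with TxW status (and optionally the FgI score, untransformed on [0, 1]) as
fixed effects and a per-mouse random intercept, fitted by Laplace-
approximate maximum likelihood (lme4). Rows with insufficient TxW history
are dropped from fitting and evaluation. Held-out predictions use the
fixed effects only (random intercept zero), the appropriate choice for
unseen animals; AUC is the Mann–Whitney concordance.

### Feature recipes

Four nested recipes feed the ML ensemble: M0 (age, diet), M1 (+ current
weight/temperature and their 30-day rolling percent change, rolled over
the date index so windows stay equidistant under missed visits), M2 (+ the
30 deficits rescaled to integers — \{0, 0.5, 1\}→\{1, 2, 3\} and
\{0, 1\}→\{1, 3\}, equalising the absent-to-severe distance across
two- and three-level items — zero-variance-filtered and reduced to 5
principal components), and M3 (+ 30-day deficit deltas, 5 further
components). Integer rescaling followed by PCA is the implemented path; a
one-hot indicator encoding is a possible alternative but was not taken, as
the rescaling description is the more specific contract. All columns are
standardized. Every learned quantity — filter, rotations, centering and
scaling — is estimated on training rows only and applied unchanged to
validation and test rows; PCA signs are pinned by making each loading's
largest element positive. Mice with under 30 days of observation and rows
with any missing input (including first visits, which have no look-back)
are excluded once, giving all recipes a common row set so their
out-of-fold predictions can be pooled.

### Splitting, tuning, stacking

25% of mouse IDs, stratified by diet, form a held-out test set; training
mice are assigned to 5 grouped CV folds, so no animal's rows ever span a
resample boundary. Event rows are up-sampled to class balance *inside each
fold's training part only* — never in validation or test rows — the
defensible reading of balance correction under cross-validation.
Candidates are four learners (regularized logistic regression via glmnet,
random forest via ranger, RBF-kernel SVM via e1071 with a deterministic
Platt-style calibration of decision values, and gradient boosting via
xgboost) crossed with the four recipes, each tuning up to 25
randomly-sampled hyperparameter configurations by grouped CV on ROC-AUC.
Racing is implemented as early elimination of configurations whose running
mean AUC after at least 3 folds trails the best by a configurable margin
(default 0.05); the per-combination winner always completes all folds, so
its out-of-fold predictions cover each training row exactly once. Full CV
(no racing) is available by flag.

Stacking pools the winners' out-of-fold predictions and fits an
L1-regularized logistic meta-model with non-negative coefficients (penalty
by grouped CV); members with non-zero weight are retained and refit on all
training rows. Attribution for the top-weighted member uses exact tree
Shapley values for xgboost and an additive-by-construction permutation
estimator otherwise. One master seed expands deterministically into split,
grid-sampling, up-sampling and learner seeds, making training
byte-reproducible and provably independent of test-mouse rows.

## Healthspan

Healthspan ends at the first assessment with four or more severe deficits
(threshold config-exposed); the event time is that assessment's age — no
interpolation between weekly visits, so a crossing hidden by a missed week
is recorded at the next observed visit, a documented convention. Mice that
die without crossing are censored at death. Curves are Kaplan–Meier,
comparisons log-rank, "maximum" healthspan the 90th percentile with the
shared quantile convention. Under a generator configuration where diet
shifts mortality but deficits accrue with chronological age, diet
separates lifespan but not healthspan — the dissociation this endpoint is
designed to expose.

## Problem sizes and numerical choices

The test-suite and acceptance runs use desk-scale sizes chosen to keep the
full pipeline re-runnable in minutes on one core while leaving each check
adequately powered: 10,000-assessment scoring oracles, 1,000-series TxW
oracles, 100-replicate mixed-model recovery at 200 mice × 20 rows,
2,000-replicate null calibrations, 300-mouse cohorts over 10 seeds for the
classifier ranking (with 2-configuration grids and the rlr/xgb learner
pair), and 20 seeds for the healthspan dissociation. Degenerate inputs are
handled explicitly: empty groups, one-class outcomes, zero-variance items,
all-tied scores, undefined predictive values (reported NA), and
separation-induced non-convergence (flagged, never silent).

## Known limitations

Correlation rows treat repeated measures as independent; the GLMM path is
Laplace-only (no quadrature); the SVM probability calibration is a single
logistic rescaling rather than libsvm's internal cross-validated fit; the
permutation Shapley estimator averages few orderings by default and is
exact only in its additivity, not per-feature; and all performance
figures quoted anywhere in this package are properties of the synthetic
generator, not of any real cohort.
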