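Package: fragility
Title: Frailty-Based Lifespan and Healthspan Endpoints for Longitudinal
    Mouse Aging Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for longitudinal frailty phenotyping in aging mouse
    cohorts. Computes Fragility Index (FgI) scores from 30-item ordinal
    deficit assessments, evaluates the temperature-by-weight (TxW)
    moving-average criterion for imminent terminal decline, labels
    assessments by proportion of life lived (PLL) and the 95PLL endpoint,
    fits mixed-effects logistic models and a stacked machine-learning
    ensemble to predict terminal decline, and derives a frailty-threshold
    healthspan endpoint with Kaplan-Meier and log-rank comparisons. A
    seeded synthetic-cohort generator with Gompertz mortality and
    ordered-logit deficit trajectories makes every stage of the pipeline
    testable without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    stats,
    utils,
    generics,
    ggplot2,
    glmnet,
    lme4,
    ranger,
    e1071,
    xgboost,
    survival,
    withr,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    car
Config/testthat/edition: 3
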