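# synthetic feature object with controllable signal, bypassing the cohort
fake_features <- function(n_mice = 100, per = 20, seed = 1) {
  set.seed(seed)
  n <- n_mice * per
  rows <- tibble::tibble(
    mouse_id = rep(sprintf("m%03d", seq_len(n_mice)), each = per),
    date = rep(as.Date("2020-01-01") + seq_len(per), n_mice),
    age_days = rnorm(n), f1 = rnorm(n), f2 = rnorm(n)
  )
  structure(list(rows = rows, base_cols = c("age_days", "f1", "f2"),
                 quant_cols = character(), item_cols = character(),
                 delta_cols = character(),
                 n_excluded = c(short_follow_mice = 0, incomplete_rows = 0)),
            class = "fgi_features")
}

fake_setup <- function(features, beta_f1 = 0, seed = 1) {
  set.seed(seed + 1)
  rows <- features$rows
  labels <- tibble::tibble(
    mouse_id = rows$mouse_id, date = rows$date,
    is_95pll = runif(nrow(rows)) < plogis(-0.5 + beta_f1 * rows$f1)
  )
  mice <- tibble::tibble(mouse_id = unique(rows$mouse_id), strain = "DO",
                         sex = "F", diet = "AL")
  split <- split_grouped(mice, seed = seed)
  list(labels = labels, split = split)
}

fake_candidate <- function(pred, learner = "rlr", recipe = "M0") {
  list(learner = learner, recipe = recipe,
       params = tibble::tibble(alpha = 1, lambda = 0.01), cv_auc = 0.8,
       oof = tibble::tibble(row = seq_along(pred), pred = pred),
       n_configs = 1, n_survivors = 1)
}

test_that("pure-noise features give chance-level CV AUC", {
  feats <- fake_features(seed = 31)
  su <- fake_setup(feats, beta_f1 = 0, seed = 31)
  cand <- suppressWarnings(
    tune_candidates(feats, su$labels, su$split, learners = "rlr",
                    recipes = "M0", grid_size = 1, seed = 31)
  )
  expect_gte(cand$rlr_M0$cv_auc, 0.45)
  expect_lte(cand$rlr_M0$cv_auc, 0.58)
})

test_that("a planted linear signal is found by regularized regression", {
  feats <- fake_features(seed = 32)
  su <- fake_setup(feats, beta_f1 = 4, seed = 32)
  cand <- suppressWarnings(
    tune_candidates(feats, su$labels, su$split, learners = "rlr",
                    recipes = "M0", grid_size = 1, seed = 32)
  )
  expect_gt(cand$rlr_M0$cv_auc, 0.9)
})

test_that("a single configuration yields complete out-of-fold coverage", {
  feats <- fake_features(n_mice = 40, per = 8, seed = 33)
  su <- fake_setup(feats, beta_f1 = 1, seed = 33)
  cand <- suppressWarnings(
    tune_candidates(feats, su$labels, su$split, learners = "rlr",
                    recipes = "M0", grid_size = 1, seed = 33)
  )$rlr_M0
  n_train <- nrow(su$split$folds |>
                    dplyr::inner_join(feats$rows, by = "mouse_id"))
  expect_equal(nrow(cand$oof), n_train)
  expect_equal(anyDuplicated(cand$oof$row), 0L)
  expect_equal(cand$n_survivors, 1)
})

test_that("stacking one candidate is a monotone transform of it", {
  set.seed(34)
  y <- runif(400) < 0.3
  pred <- plogis(qlogis(0.3) + 2 * (y - 0.3) + rnorm(400, 0, 0.5))
  st <- stack_candidates(list(solo = fake_candidate(pred)), y,
                         foldid = rep_len(1:5, 400))
  meta <- fragility:::predict_meta(st, tibble::tibble(solo = pred))
  expect_equal(cor(meta, pred, method = "spearman"), 1)
  expect_true(all(st$weights > 0))
})

test_that("duplicated candidates do not change the stacked AUC", {
  set.seed(35)
  y <- runif(400) < 0.3
  pred <- plogis(qlogis(0.3) + 2 * (y - 0.3) + rnorm(400, 0, 0.5))
  one <- stack_candidates(list(a = fake_candidate(pred)), y,
                          foldid = rep_len(1:5, 400))
  two <- stack_candidates(list(a = fake_candidate(pred),
                               b = fake_candidate(pred)), y,
                          foldid = rep_len(1:5, 400))
  auc1 <- roc_auc(fragility:::predict_meta(
    one, tibble::tibble(a = pred)), y)$auc
  auc2 <- roc_auc(fragility:::predict_meta(
    two, tibble::tibble(a = pred, b = pred)), y)$auc
  expect_equal(auc1, auc2)
})

test_that("the fitted ensemble keeps only positively weighted members", {
  ens <- test_ensemble()
  expect_true(all(ens$stack$weights > 0))
  expect_setequal(names(ens$members), names(ens$stack$weights))
  td <- tidy(ens)
  expect_true(all(td$weight[!td$member %in% names(ens$members)] == 0))
  # predictions are probabilities
  co <- test_cohort_do()
  pr <- predict(ens, co$assessments, co$mice)
  expect_true(all(pr$prob > 0 & pr$prob < 1))
})

test_that("threshold metrics follow their definitions", {
  y <- c(rep(TRUE, 50), rep(FALSE, 150))
  perfect <- ifelse(y, 0.99, 0.01)
  rep1 <- evaluate_classifier(perfect, y)
  expect_true(all(rep1$metrics$accuracy == 1))
  expect_equal(rep1$auc_roc, 1)
  expect_equal(rep1$auc_pr, 1)

  set.seed(36)
  y2 <- sample(y)
  rep2 <- evaluate_classifier(runif(2000), runif(2000) < 0.3)
  expect_gt(rep2$auc_roc, 0.45)
  expect_lt(rep2$auc_roc, 0.55)

  # a calibrated score has (weakly) increasing precision in the threshold
  set.seed(37)
  p <- runif(20000)
  yy <- runif(20000) < p
  rep3 <- evaluate_classifier(p, yy)
  expect_true(all(diff(rep3$metrics$ppv) > -0.02))
  expect_error(evaluate_classifier(runif(5), rep(TRUE, 5)), "both classes")
})

test_that("every learner wrapper fits, predicts probabilities, and repeats", {
  set.seed(38)
  x <- cbind(a = rnorm(300), b = rnorm(300), c = rnorm(300))
  y <- runif(300) < plogis(1.5 * x[, "a"])
  grids <- lapply(fragility:::learner_ids(), fragility:::learner_grid,
                  grid_size = 1, seed = 3)
  names(grids) <- fragility:::learner_ids()
  for (lr in fragility:::learner_ids()) {
    f1 <- fragility:::fit_learner(lr, x, y, grids[[lr]][1, ], seed = 5)
    f2 <- fragility:::fit_learner(lr, x, y, grids[[lr]][1, ], seed = 5)
    p1 <- fragility:::predict_learner(f1, x)
    p2 <- fragility:::predict_learner(f2, x)
    expect_true(all(p1 >= 0 & p1 <= 1), label = lr)
    expect_identical(p1, p2, label = paste(lr, "determinism"))
    expect_gt(roc_auc(p1, y)$auc, 0.6, label = paste(lr, "signal"))
  }
})
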