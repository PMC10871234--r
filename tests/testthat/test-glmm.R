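# simulate rows from the logistic mixed model itself
simulate_glmm_rows <- function(n_mice = 200, n_obs = 20, b0 = -2.5,
                               b_txw = 2, b_fgi = 3, re_sd = 1) {
  u <- rnorm(n_mice, 0, re_sd)
  tibble::tibble(
    mouse_id = rep(sprintf("m%03d", seq_len(n_mice)), each = n_obs),
    txw_fail = runif(n_mice * n_obs) < 0.25,
    fgi_score = runif(n_mice * n_obs, 0, 0.6),
    u = rep(u, each = n_obs)
  ) |>
    dplyr::mutate(is_95pll = runif(dplyr::n()) <
                    plogis(b0 + b_txw * txw_fail + b_fgi * fgi_score + u)) |>
    dplyr::select(-u)
}

test_that("a single simulated dataset recovers the generating coefficients", {
  set.seed(14)
  rows <- simulate_glmm_rows()
  fit <- fit_95pll_glmm(rows)
  expect_true(fit$converged)
  td <- tidy(fit)
  b_txw <- td[td$term == "txw_failTRUE", ]
  b_fgi <- td[td$term == "fgi_score", ]
  expect_true(b_txw$conf_low < 2 && 2 < b_txw$conf_high)
  expect_true(b_fgi$conf_low < 3 && 3 < b_fgi$conf_high)
  expect_lt(abs(fit$random_intercept_sd - 1), 0.35)
  g <- glance(fit)
  expect_equal(g$n_mice, 200L)
})

test_that("degenerate inputs are refused", {
  rows <- tibble::tibble(mouse_id = rep(c("a", "b"), each = 5),
                         txw_fail = rep(c(TRUE, FALSE), 5),
                         fgi_score = runif(10),
                         is_95pll = TRUE)
  expect_error(fit_95pll_glmm(rows), "single class")
  one_mouse <- dplyr::mutate(rows, mouse_id = "a",
                             is_95pll = rep(c(TRUE, FALSE), 5))
  expect_error(fit_95pll_glmm(one_mouse), "2 mice")
})

test_that("fixed-effects prediction is the closed-form inverse logit", {
  fake <- structure(
    list(coef = c("(Intercept)" = -2, "txw_failTRUE" = 1),
         include_fgi = FALSE, converged = TRUE),
    class = "glmm_95pll"
  )
  rows <- tibble::tibble(mouse_id = c("x", "y"), txw_fail = c(TRUE, FALSE),
                         is_95pll = c(TRUE, FALSE))
  p <- predict_fixed(fake, rows)
  expect_equal(p, plogis(c(-1, -2)))

  null_fit <- structure(
    list(coef = c("(Intercept)" = 0, "txw_failTRUE" = 0),
         include_fgi = FALSE, converged = TRUE),
    class = "glmm_95pll"
  )
  expect_equal(predict_fixed(null_fit, rows), c(0.5, 0.5))

  # positive FgI coefficient implies strictly increasing probability
  with_fgi <- structure(
    list(coef = c("(Intercept)" = -2, "txw_failTRUE" = 1,
                  "fgi_score" = 4),
         include_fgi = TRUE, converged = TRUE),
    class = "glmm_95pll"
  )
  grid <- tibble::tibble(mouse_id = "x", txw_fail = FALSE,
                         fgi_score = seq(0, 1, 0.1), is_95pll = FALSE)
  expect_true(all(diff(predict_fixed(with_fgi, grid)) > 0))
})

test_that("prediction ignores the mouse identifier entirely", {
  set.seed(15)
  rows <- simulate_glmm_rows(n_mice = 40, n_obs = 10)
  fit <- fit_95pll_glmm(rows)
  p1 <- predict_fixed(fit, rows)
  shuffled <- dplyr::mutate(rows, mouse_id = sample(mouse_id))
  expect_identical(p1, predict_fixed(fit, shuffled))
})

test_that("AUC equals Mann-Whitney concordance and closed-form cases", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.7, 0.1), c(1, 1, 0, 0))$auc, 1)
  expect_equal(roc_auc(c(1, 1, 0, 0), c(1, 1, 0, 0))$auc, 1)
  expect_equal(roc_auc(rep(0.5, 10), rep(c(0, 1), 5))$auc, 0.5)  # all tied
  set.seed(16)
  p <- runif(10000); y <- runif(10000) < 0.3
  expect_lt(abs(roc_auc(p, y)$auc - 0.5), 0.02)
  expect_error(roc_auc(runif(5), rep(TRUE, 5)), "both classes")

  # agreement with an independent implementation
  p2 <- runif(300); y2 <- runif(300) < 0.4
  expect_equal(roc_auc(p2, y2)$auc,
               as.numeric(pROC::auc(pROC::roc(
                 y2, p2, quiet = TRUE, direction = "<",
                 levels = c(FALSE, TRUE)
               ))))
})

test_that("a binary score's AUC equals its single-threshold identity", {
  set.seed(17)
  flag <- runif(500) < 0.3
  y <- runif(500) < plogis(-1 + 2 * flag)
  sens <- mean(flag[y]); spec <- mean(!flag[!y])
  expect_equal(roc_auc(as.numeric(flag), y)$auc, (1 + sens - (1 - spec)) / 2)
})

test_that("PR-AUC is exact for a perfect ranking and sane under noise", {
  expect_equal(pr_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  set.seed(18)
  y <- runif(5000) < 0.2
  expect_lt(abs(pr_auc(runif(5000), y) - 0.2), 0.05)
})
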