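test_that("PLL labelling is exact arithmetic with a strict 0.95 boundary", {
  mice <- tibble::tibble(mouse_id = c("a", "b", "c"),
                         lifespan_days = c(1000, 1000, 1000))
  a <- tibble::tibble(
    mouse_id = c("a", "b", "c"),
    date = as.Date("2020-01-01") + 0:2,
    age_days = c(1000, 950, 960)
  )
  l <- label_assessments(a, mice)
  expect_equal(l$pll, c(1, 0.95, 0.96))
  expect_equal(l$is_95pll, c(TRUE, FALSE, TRUE))
  expect_equal(l$life_expectancy_days, c(0, 50, 40))

  bad <- dplyr::mutate(a, age_days = age_days + 100)
  expect_error(label_assessments(bad, mice), "exceeds lifespan")
})

test_that("labels are reproducible bit-for-bit from age and lifespan", {
  co <- test_cohort()
  l <- label_assessments(co$assessments, co$mice)
  j <- dplyr::inner_join(l, co$mice[c("mouse_id", "lifespan_days")],
                         by = "mouse_id")
  expect_identical(l$pll, j$age_days / j$lifespan_days)
  expect_identical(l$is_95pll, j$age_days / j$lifespan_days > 0.95)
  expect_identical(l$life_expectancy_days, j$lifespan_days - j$age_days)
})

test_that("lifespan summaries use the linear-interpolation quantile rule", {
  m <- tibble::tibble(lifespan_days = c(10, 20, 30))
  s <- summarize_lifespan(m)
  expect_equal(s$median, 20)

  m10 <- tibble::tibble(lifespan_days = 1:10)
  expect_equal(summarize_lifespan(m10)$p90, 9.1)

  one <- tibble::tibble(lifespan_days = 500)
  s1 <- summarize_lifespan(one)
  expect_true(all(unlist(s1[c("median", "q1", "q3", "p90")]) == 500))

  grp <- tibble::tibble(lifespan_days = 1:6, g = rep(c("x", "y"), 3))
  expect_equal(nrow(summarize_lifespan(grp, "g")), 2)
})

test_that("the quantile test of proportions behaves at both extremes", {
  # no signal: two identical groups
  v <- rep(c(1:50), 2)
  g <- rep(c("a", "b"), each = 50)
  qt <- quantile_test(v, g, q = 0.9)
  expect_gt(qt$p_value, 0.99)

  # complete separation at the pooled 90th percentile
  v2 <- c(rnorm(50, 0), rnorm(50, 100))
  qt2 <- quantile_test(v2, rep(c("lo", "hi"), each = 50), q = 0.9)
  expect_lt(qt2$p_value, 0.001)

  expect_error(quantile_test(rep(1, 20), rep(c("a", "b"), 10)), "degenerate")
  expect_error(quantile_test(1:5, rep("a", 5)), "2 groups")
})

test_that("the median-deviation variance test matches Brown-Forsythe", {
  # fixed table, independently computed with car::leveneTest(center = median)
  set.seed(3)
  v <- c(rnorm(30, sd = 1), rnorm(30, sd = 3))
  g <- rep(c("a", "b"), each = 30)
  ours <- median_deviation_variance_test(v, g)
  ref <- car::leveneTest(v ~ factor(g), center = median)
  expect_equal(ours$statistic, ref$`F value`[1])
  expect_equal(ours$p_value, ref$`Pr(>F)`[1])

  # equal spread: not significant; 3:1 SD ratio at n = 100: significant
  set.seed(4)
  same <- median_deviation_variance_test(rnorm(200), rep(c("a", "b"), 100))
  expect_gt(same$p_value, 0.1)
  diff3 <- median_deviation_variance_test(
    c(rnorm(100, sd = 3), rnorm(100, sd = 1)), rep(c("a", "b"), each = 100)
  )
  expect_lt(diff3$p_value, 0.01)

  expect_error(median_deviation_variance_test(c(1, 2, 3), c("a", "a", "b")),
               "at least 2 values")
})

test_that("life-expectancy correlations recover planted structure", {
  cat30 <- deficit_catalog()
  n <- 400
  set.seed(8)
  mice <- tibble::tibble(mouse_id = sprintf("m%04d", 1:n), strain = "DO",
                         sex = "F", diet = "AL", lifespan_days = 1200)
  a <- blank_assessments(n, cat30, mouse_id = mice$mouse_id,
                         age_days = round(seq(800, 1199, length.out = n)))
  le <- 1200 - a$age_days
  # tumors tracks -LE exactly through a monotone rescaling to {0, 0.5, 1}
  a$tumors <- c(0, 0.5, 1)[cut(-le, 3, labels = FALSE)]
  a$tremor <- sample(c(0, 0.5, 1), n, replace = TRUE)  # independent noise
  rows <- deficit_le_correlations(a, mice, cat30, group_by = "strain")
  expect_lt(rows$r[rows$variable == "Tumors"], -0.85)
  expect_lt(abs(rows$r[rows$variable == "Tremor"]), 0.15)
  # zero-variance items yield blank rows, sorted last
  expect_true(is.na(rows$r[rows$variable == "Kyphosis"]))
  expect_true(all(is.na(rows$r[rows$variable == "Nasal Discharge"])))
  # CI brackets the estimate
  ok <- !is.na(rows$r)
  expect_true(all(rows$ci_low[ok] <= rows$r[ok] &
                    rows$r[ok] <= rows$ci_high[ok]))
  # age is perfectly anticorrelated with LE in this construction
  expect_equal(rows$variable[1], "Age")
  expect_equal(rows$r[1], -1)
})

test_that("an exactly anti-proportional item gives r = -1", {
  cat30 <- deficit_catalog()
  mice <- tibble::tibble(mouse_id = sprintf("m%d", 1:90), strain = "B6",
                         sex = "F", diet = "AL", lifespan_days = 1000)
  a <- blank_assessments(90, cat30, mouse_id = mice$mouse_id,
                         age_days = rep(c(900, 950, 1000), 30))
  a$activity <- rep(c(0, 0.5, 1), 30)  # rises linearly as LE falls linearly
  rows <- deficit_le_correlations(a, mice, cat30, group_by = "strain")
  expect_equal(rows$r[rows$variable == "Activity"], -1, tolerance = 1e-12)
})

test_that("Fisher-z intervals achieve near-nominal coverage", {
  set.seed(12)
  true_r <- 0.4
  n <- 500
  covered <- replicate(500, {
    x <- rnorm(n)
    y <- true_r * x + sqrt(1 - true_r^2) * rnorm(n)
    ci <- cor.test(x, y)$conf.int
    ci[1] <= true_r && true_r <= ci[2]
  })
  expect_gte(mean(covered), 0.93)
})
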