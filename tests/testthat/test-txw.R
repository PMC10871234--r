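make_series <- function(offsets, values, id = "m1",
                        origin = as.Date("2021-06-01")) {
  tibble::tibble(mouse_id = id, date = origin + offsets,
                 weight_g = values / 37, temp_C = 37)
}

test_that("the TxW product is exact and propagates missingness", {
  expect_equal(txw(30, 37), 1110)
  expect_equal(txw(25, 30), 750)
  expect_true(is.na(txw(NA, 37)))
  expect_true(is.na(txw(30, NA)))
  expect_error(txw(-1, 37), "positive")
})

test_that("window means, the fail boundary and insufficiency are correct", {
  # 13 weekly visits of constant TxW: zero change, pass
  const <- make_series(seq(0, 84, by = 7), rep(1110, 13))
  st <- evaluate_txw(const)
  last <- st[st$date == max(st$date), ]
  expect_equal(last$pct_change, 0)
  expect_equal(last$flag, "pass")

  # benchmark {1000 x 4} at -84..-63 days, recent {890, 900}
  s <- make_series(c(-84, -77, -70, -63, -7, 0) + 84,
                   c(1000, 1000, 1000, 1000, 890, 900))
  st2 <- evaluate_txw(s)
  row <- st2[st2$date == max(st2$date), ]
  expect_equal(row$benchmark_mean, 1000)
  expect_equal(row$recent_mean, 895)
  expect_equal(row$pct_change, -10.5)
  expect_equal(row$flag, "fail")

  # exactly -10% is a fail (inclusive boundary)
  s3 <- make_series(c(-84, -77, -70, -63, -7, 0) + 84,
                    c(1000, 1000, 1000, 1000, 900, 900))
  expect_equal(evaluate_txw(s3)$flag[6], "fail")

  # only 6 weeks of history: benchmark window empty
  short <- make_series(seq(0, 42, by = 7), rep(1110, 7))
  expect_true(all(evaluate_txw(short)$flag == "insufficient"))

  dup <- make_series(c(0, 0), c(1000, 1000))
  expect_error(evaluate_txw(dup), "duplicate")
})

test_that("pct change and flags are invariant to rescaling the series", {
  set.seed(5)
  offsets <- sort(sample(0:120, 15))
  s <- make_series(offsets, runif(15, 900, 1200))
  a <- evaluate_txw(s)
  s2 <- dplyr::mutate(s, weight_g = weight_g * 3.7)
  b <- evaluate_txw(s2)
  expect_equal(a$flag, b$flag)
  expect_equal(a$pct_change, b$pct_change)
})

test_that("evaluate_txw matches a brute-force oracle on random series", {
  set.seed(99)
  oracle_one <- function(day, v, i) {
    bench <- v[day > day[i] - 91 & day <= day[i] - 63 & !is.na(v)]
    recent <- v[day > day[i] - 21 & day <= day[i] & !is.na(v)]
    if (length(bench) < 2 || length(recent) < 2) return("insufficient")
    if (100 * (mean(recent) - mean(bench)) / mean(bench) <= -10) "fail"
    else "pass"
  }
  for (rep in 1:100) {
    n <- sample(5:30, 1)
    offsets <- sort(sample(0:200, n))
    v <- runif(n, 600, 1400)
    v[runif(n) < 0.15] <- NA
    s <- tibble::tibble(mouse_id = "m", date = as.Date("2021-01-01") + offsets,
                        weight_g = v / 37, temp_C = 37)
    got <- evaluate_txw(s)$flag
    day <- offsets
    want <- vapply(seq_len(n), function(i) oracle_one(day, v, i), "")
    expect_identical(got, want)
  }
})

test_that("PPV and NPV are exact contingency arithmetic", {
  status <- function(flags) {
    tibble::tibble(mouse_id = "m", date = as.Date("2020-01-01") +
                     seq_along(flags), flag = flags)
  }
  lbl <- function(truth) {
    tibble::tibble(mouse_id = "m", date = as.Date("2020-01-01") +
                     seq_along(truth), is_95pll = truth)
  }
  mice <- tibble::tibble(mouse_id = "m", strain = "DO")

  # all correct
  st <- status(c("fail", "fail", "pass", "pass"))
  v <- validate_txw(st, lbl(c(TRUE, TRUE, FALSE, FALSE)), mice)
  expect_equal(c(v$ppv, v$npv), c(1, 1))

  # tp 3 fp 1 tn 90 fn 6
  flags <- c(rep("fail", 4), rep("pass", 96))
  truth <- c(rep(TRUE, 3), FALSE, rep(FALSE, 90), rep(TRUE, 6))
  v2 <- validate_txw(status(flags), lbl(truth), mice)
  expect_equal(unlist(v2[c("tp", "fp", "tn", "fn")], use.names = FALSE),
               c(3, 1, 90, 6))
  expect_equal(v2$ppv, 0.75)
  expect_equal(v2$npv, 0.9375)

  # no positive predictions: PPV undefined
  v3 <- validate_txw(status(c("pass", "pass")), lbl(c(FALSE, TRUE)), mice)
  expect_true(is.na(v3$ppv))
  expect_equal(v3$npv, 0.5)

  # insufficient rows are excluded before counting
  v4 <- validate_txw(status(c("insufficient", "pass")),
                     lbl(c(TRUE, FALSE)), mice)
  expect_equal(v4$tn, 1)
  expect_equal(v4$tp + v4$fp + v4$fn, 0)
})

test_that("TxW flags localize to the terminal window in a planted cohort", {
  co <- cached("cohort_txw_loc", simulate_cohort(cohort_config(
    n_mice_per_group = 10, strains = "DO", terminal_drop_cv = 0,
    weight_wander_sd_g = 0.1, weight_noise_sd_g = 0.3, seed = 71
  )))
  st <- evaluate_txw(co$assessments)
  l <- label_assessments(co$assessments, co$mice)
  d <- dplyr::inner_join(dplyr::filter(st, flag != "insufficient"),
                         l, by = c("mouse_id", "date"))
  sens_late <- mean(d$flag[d$pll > 0.95] == "fail")
  sens_early <- mean(d$flag[d$pll < 0.8] == "fail")
  expect_gt(sens_late, sens_early)
})
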