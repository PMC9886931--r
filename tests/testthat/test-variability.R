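test_that("lcv computes mean, population CV and log10 CV", {
  s <- lcv(c(90, 100, 110))
  expect_equal(s$M, 100)
  expect_equal(s$CV, sqrt(200 / 3) / 100, tolerance = 1e-10)  # 0.0816497
  expect_equal(s$LCV, log10(sqrt(200 / 3) / 100), tolerance = 1e-10)  # -1.0880
  expect_equal(round(s$LCV, 4), -1.0880)
})

test_that("degenerate and invalid series raise classed errors", {
  expect_error(lcv(c(5, 5, 5)), class = "varnet_degenerate_error")
  expect_error(lcv(7), class = "varnet_input_error")
  expect_error(lcv(c(-10, -20)), class = "varnet_input_error")
})

test_that("CV and LCV are invariant to positive rescaling", {
  set.seed(1)
  x <- rlnorm(30, 4, 0.2)
  base <- lcv(x)
  for (c_ in c(0.01, 3.7, 1000)) {
    s <- lcv(c_ * x)
    expect_equal(s$CV, base$CV, tolerance = 1e-12)
    expect_equal(s$LCV, base$LCV, tolerance = 1e-12)
  }
})

test_that("population-SD convention uses the n divisor", {
  expect_equal(varnet:::pop_sd(c(0, 1)), 0.5)  # not 0.7071
  s <- lcv(c(0.5, 1.5))
  expect_equal(s$CV, 0.5)
})

test_that("windows aggregate per calendar month and per year", {
  days <- as.Date(sprintf("2020-%02d-%02d", rep(1:12, each = 2), c(5, 19)))
  set.seed(2)
  rec <- data.frame(patient_id = "P1", date = days, biomarker = "BUN",
                    value = rnorm(24, 60, 6))
  mo <- variability_summary(rec, "month")
  expect_equal(nrow(mo), 12L)
  expect_true(all(mo$n == 2))
  yr <- variability_summary(rec, "year")
  expect_equal(nrow(yr), 1L)
  expect_equal(yr$n, 24L)
  ## yearly summary equals the direct pooled computation
  direct <- lcv(rec$value)
  expect_equal(yr$M, direct$M)
  expect_equal(yr$CV, direct$CV, tolerance = 1e-12)
  expect_equal(yr$LCV, direct$LCV, tolerance = 1e-12)
})

test_that("underfilled or constant windows are omitted with a warning", {
  rec <- data.frame(patient_id = "P1",
                    date = as.Date(c("2020-01-05", "2020-02-05", "2020-02-19")),
                    biomarker = "TP", value = c(6.1, 6.3, 6.2))
  expect_warning(mo <- variability_summary(rec, "month"), "omitted")
  expect_equal(mo$window, "2020-02")
  rec$value <- c(6, 6, 6)
  expect_warning(out <- variability_summary(rec, "month"), "omitted")
  expect_equal(nrow(out), 0L)
})

test_that("monthly means of a seasonal biomarker trace the injected cosine", {
  sp <- small_spec("SBP", n_patients = 200)
  coh <- simulate_cohort(sp, seed = 21)
  ms <- suppressWarnings(variability_summary(coh$records, "month"))
  prof <- tapply(ms$M, ms$window, mean)
  month <- as.integer(sub("2020-", "", names(prof)))
  expected <- mean(prof) + 3.9 * cos(2 * pi * (month - 2) / 12)
  expect_lt(max(abs(prof - expected)), 1.5)  # n=200 noise on monthly means
  expect_gt(cor(prof, expected), 0.95)
})

test_that("eligibility requires >100 sessions, >21 tests and 6-month vintage", {
  md <- data.frame(patient_id = c("A", "B", "C", "D", "E"),
                   sessions = c(100, 150, 150, 150, 101),
                   tests_attended = c(24, 22, 21, 24, 24),
                   vintage_years = c(2, 2, 2, 0.4, 0.5))
  keep <- eligibility_filter(md)
  expect_setequal(keep, c("B", "E"))  # A: sessions==100 out; C: tests==21 out
  expect_error(eligibility_filter(md[, -2]), regexp = "sessions",
               class = "varnet_input_error")
})

test_that("paired month comparison handles identical and degenerate inputs", {
  ms <- data.frame(patient_id = rep(c("P1", "P2", "P3"), 2),
                   window = rep(c("2020-02", "2020-08"), each = 3),
                   M = c(10, 11, 12, 10, 11, 12), LCV = rnorm(6))
  out <- paired_month_test(ms, 2, 8, "M")
  expect_equal(out$t, 0)
  expect_equal(out$p, 1)
  ms$M[4:6] <- ms$M[1:3] - 1  # constant non-zero differences
  expect_error(paired_month_test(ms, 2, 8, "M"),
               class = "varnet_degenerate_error")
  expect_error(paired_month_test(ms[1:4, ], 3, 8, "M"),
               class = "varnet_input_error")
})

test_that("KS normality check behaves across null, skewed and exact inputs", {
  ## estimated-parameter KS is conservative under the null
  set.seed(11)
  rej <- vapply(1:200, function(i) ks_normality(rnorm(334))$rejected,
                logical(1))
  expect_lt(mean(rej), 0.05)
  ## heavy skew is rejected
  set.seed(12)
  expect_true(ks_normality(rlnorm(334, 0, 1))$rejected)
  ## exact normal quantiles are not rejected
  expect_false(ks_normality(qnorm(ppoints(334)))$rejected)
  expect_error(ks_normality(rep(1, 20)), class = "varnet_degenerate_error")
  expect_error(ks_normality(rnorm(5)), class = "varnet_input_error")
})

test_that("Monte-Carlo calibrated KS variant is available", {
  set.seed(13)
  x <- rnorm(120)
  out <- ks_normality(x, monte_carlo = TRUE, n_reps = 200, seed = 3)
  expect_true(out$p > 0 && out$p <= 1)
})
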