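test_that("identical spec and seed give byte-identical cohorts", {
  sp <- small_spec(c("BUN", "Cr", "Na"), n_patients = 30)
  a <- simulate_cohort(sp, seed = 7)
  b <- simulate_cohort(sp, seed = 7)
  expect_identical(a$records, b$records)
  expect_identical(a$metadata, b$metadata)
  expect_identical(a$truth, b$truth)
  c2 <- simulate_cohort(sp, seed = 8)
  expect_false(identical(a$records$value, c2$records$value))
})

test_that("a seed is mandatory and a non-PSD factor correlation is caught", {
  sp <- small_spec(c("BUN", "Cr"), n_patients = 10)
  expect_error(simulate_cohort(sp), class = "varnet_seed_error")
  sp_bad <- sp
  sp_bad$factor_corr[1, 2] <- sp_bad$factor_corr[2, 1] <- 2
  expect_error(simulate_cohort(sp_bad, seed = 1), class = "varnet_spec_error")
})

test_that("records respect positivity, the study year and the schedules", {
  coh <- cached_cohort(1)
  sp <- coh$spec
  expect_true(all(coh$records$value > 0))
  yrs <- format(as.Date(coh$records$date), "%Y")
  expect_true(all(yrs == "2020"))
  counts <- table(coh$records$patient_id, coh$records$biomarker)
  for (b in setdiff(sp$biomarkers, sp$hemodynamic))
    expect_true(all(counts[, b] == sp$schedule[b]))
  hemo_counts <- counts[, sp$hemodynamic]
  expect_true(all(hemo_counts >= 12 & hemo_counts <= 159))
  expect_gt(median(hemo_counts[, "SBP"]), 120)
})

test_that("noise-free degenerate spec returns the intercepts as LCVs", {
  L0 <- hd_panel_loadings()[c("BUN", "Cr"), , drop = FALSE]
  L0[] <- 0
  sp <- cohort_spec(n_patients = 15, loadings = L0,
                    lcv_sd = c(BUN = 1e-6, Cr = 1e-6),
                    hemodynamic = character(),
                    absorb_sampling_noise = FALSE)
  coh <- simulate_cohort(sp, seed = 3)
  for (b in c("BUN", "Cr"))
    expect_true(all(abs(coh$truth$lcv[, b] - sp$lcv_intercepts[b]) < 1e-5))
})

test_that("two indicators of one factor reproduce the population correlation", {
  ## lambda = 0.8 each, unit total LCV variance -> corr = 0.64
  L <- matrix(0, 2, 6, dimnames = list(c("BUN", "Cr"),
                                       colnames(hd_panel_loadings())))
  L[, "metabolism"] <- 0.8
  sp <- cohort_spec(n_patients = 20000, loadings = L,
                    lcv_sd = c(BUN = 1, Cr = 1),
                    hemodynamic = character(),
                    absorb_sampling_noise = FALSE)
  coh <- simulate_cohort(sp, seed = 42)
  r <- cor(coh$truth$lcv[, "BUN"], coh$truth$lcv[, "Cr"])
  expect_lt(abs(r - 0.64), 0.02)
})

test_that("marginal LCV means and SDs are recovered at the study size", {
  sp <- cohort_spec()
  L <- cached_lcv(1)[, sp$biomarkers]
  z_mean <- (colMeans(L) - sp$lcv_mean) / (sp$lcv_sd / sqrt(334))
  z_sd <- (apply(L, 2, sd) - sp$lcv_sd) / (sp$lcv_sd / sqrt(2 * 334))
  expect_true(all(abs(z_mean) < 4))
  expect_true(all(abs(z_sd) < 4))
  ## paper-anchored spot value: SBP variability
  expect_lt(abs(mean(L[, "SBP"]) - (-0.99)), 3 * 0.10 / sqrt(334))
})

test_that("sample LCV correlations track the implied correlation matrix", {
  sp <- cohort_spec()
  L <- cached_lcv(1)[, sp$biomarkers]
  R_obs <- cor(L)
  R_pop <- implied_lcv_cov(sp, standardized = TRUE)
  expect_lt(max(abs(R_obs - R_pop)), 4 / sqrt(334))
})

test_that("seasonal component shifts monthly means as a cosine", {
  days <- as.Date(sprintf("2020-%02d-15", 1:12))
  rec <- data.frame(patient_id = "P1", date = rep(days, each = 2),
                    biomarker = "SBP", value = c(150, 152))
  out <- add_seasonal_component(rec, "SBP", amplitude = 0)
  expect_identical(out, rec)
  out <- add_seasonal_component(rec, "SBP", amplitude = 3.9, peak_month = 2)
  ms <- suppressWarnings(variability_summary(out, "month"))
  feb <- ms$M[ms$window == "2020-02"]
  aug <- ms$M[ms$window == "2020-08"]
  expect_equal(feb - aug, 7.8, tolerance = 1e-10)
  ## moving the peak to August flips the sign of the contrast
  out2 <- add_seasonal_component(rec, "SBP", amplitude = 3.9, peak_month = 8)
  ms2 <- suppressWarnings(variability_summary(out2, "month"))
  expect_equal(ms2$M[ms2$window == "2020-02"] - ms2$M[ms2$window == "2020-08"],
               -7.8, tolerance = 1e-10)
  expect_error(add_seasonal_component(rec, "nope", 1),
               class = "varnet_spec_error")
})

test_that("winter blood-pressure cycle is detected by the paired test", {
  ## paired February-vs-August test on simulated cohorts: the configured
  ## SBP amplitude must be detectable in essentially every run
  hits <- logical(6)
  sp <- small_spec("SBP", n_patients = 334)
  for (s in seq_along(hits)) {
    coh <- simulate_cohort(sp, seed = 400 + s)
    ms <- suppressWarnings(variability_summary(coh$records, "month"))
    tst <- paired_month_test(ms, 2, 8, "M")
    hits[s] <- tst$p < 0.001 && tst$diff > 0
  }
  expect_true(all(hits))
})

test_that("cohorts round-trip through the CSV writers", {
  coh <- simulate_cohort(small_spec(c("BUN", "Na"), n_patients = 12), seed = 5)
  d <- withr::local_tempdir()
  write_cohort(coh, d)
  expect_setequal(list.files(d), c("records.csv", "metadata.csv",
                                   "truth_eta.csv", "truth_lcv.csv"))
  rec <- read.csv(file.path(d, "records.csv"))
  expect_equal(nrow(rec), nrow(coh$records))
  expect_equal(rec$value, coh$records$value)
  expect_match(rec$date[1], "^2020-[0-9]{2}-[0-9]{2}$")
})

test_that("lognormal measurement noise preserves the mean-CV calibration", {
  sp <- small_spec(c("BUN", "Cr"), n_patients = 60,
                   measurement_dist = "lognormal")
  coh <- simulate_cohort(sp, seed = 9)
  expect_true(all(coh$records$value > 0))
  L <- lcv_matrix(coh)
  ## realized LCVs still centred near the targets
  expect_lt(abs(mean(L[, "BUN"]) - sp$lcv_mean["BUN"]),
            4 * sp$lcv_sd["BUN"] / sqrt(60))
})
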