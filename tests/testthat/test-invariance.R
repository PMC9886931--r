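test_that("delta-df identities hold for arbitrary model shapes", {
  shapes <- list(
    default_cfa_model(),
    cfa_model(list(A = c("a1", "a2", "a3"), B = c("b1", "b2", "b3"))),
    cfa_model(list(A = c("a1", "a2", "a3", "a4"), B = c("b1", "b2"),
                   C = c("c1", "c2", "c3")),
              cross = list(c("a1", "B")))
  )
  for (m in shapes) {
    df <- vapply(c("configural", "metric", "scalar", "strict"),
                 function(lv) model_df(m, 2, TRUE, lv), integer(1))
    p <- length(m$indicators); nf <- length(m$factors); nl <- m$n_loadings
    expect_equal(unname(df["metric"] - df["configural"]), nl - nf)
    expect_equal(unname(df["scalar"] - df["metric"]), p - nf)
    expect_equal(unname(df["strict"] - df["scalar"]), p)
    expect_true(all(diff(df) > 0))
  }
  ## the default model reproduces the printed delta-df ladder
  m <- default_cfa_model()
  expect_equal(model_df(m, 2, TRUE, "metric") - model_df(m, 2, TRUE, "configural"), 12L)
  expect_equal(model_df(m, 2, TRUE, "scalar") - model_df(m, 2, TRUE, "metric"), 10L)
  expect_equal(model_df(m, 2, TRUE, "strict") - model_df(m, 2, TRUE, "scalar"), 16L)
})

test_that("ladder statistics are non-decreasing and identical groups pass", {
  ## two groups drawn from one parameter set: a random split of one cohort
  L <- cached_lcv(2)
  set.seed(77)
  g <- sample(rep(c("g1", "g2"), length.out = nrow(L)))
  inv <- invariance_ladder(default_cfa_model(), L, g)
  expect_equal(inv$grid$level, c("configural", "metric", "scalar", "strict"))
  expect_true(all(diff(inv$grid$chisq) >= -1e-6))
  expect_true(all(diff(inv$grid$df) > 0))
  expect_equal(inv$achieved, "strict")
  fm <- compare_factor_means(inv, "strict")
  expect_true(all(fm$p > 0.001))
  expect_lt(max(abs(fm$estimate)), 0.5)
  ## unconstrained two-group fit equals two independent single-group fits
  conf <- inv$fits$configural
  f1 <- cfa(default_cfa_model(), data = L[g == "g1", ], mean_structure = TRUE,
            se = FALSE)
  f2 <- cfa(default_cfa_model(), data = L[g == "g2", ], mean_structure = TRUE,
            se = FALSE)
  expect_equal(conf$statistic, f1$statistic + f2$statistic, tolerance = 1e-4)
  expect_equal(conf$df, f1$df + f2$df)
})

test_that("invariance decisions follow the delta-fit-index thresholds", {
  mk <- function(dcfi, dtli, drmsea) {
    data.frame(comparison = c("metric-configural", "scalar-metric",
                              "strict-scalar"),
               delta_CFI = dcfi, delta_TLI = dtli, delta_RMSEA = drmsea)
  }
  ## small degradations pass every step
  expect_equal(evaluate_invariance(mk(c(-0.003, -0.007, -0.005),
                                      c(0.001, -0.006, -0.002),
                                      c(0.000, 0.003, 0.001))), "strict")
  ## a -0.025 CFI drop at the strict step stops at scalar
  expect_equal(evaluate_invariance(mk(c(-0.002, -0.008, -0.025),
                                      c(0.001, -0.007, -0.025),
                                      c(0.000, 0.003, 0.010))), "scalar")
  ## all-zero deltas reach the deepest fitted level
  expect_equal(evaluate_invariance(mk(0, 0, 0)), "strict")
  ## RMSEA inflation alone can stop the ladder
  expect_equal(evaluate_invariance(mk(0, 0, c(0.02, 0, 0))), "configural")
  expect_equal(evaluate_invariance(NULL), "configural")
})

test_that("factor-mean contrasts use Wald z on the group-2 means", {
  fake <- structure(list(
    fits = list(strict = list(
      estimates = c("alpha:metabolism@g2" = 0.049, "alpha:salt@g2" = 0),
      se = c(0.014, 0.02))),
    achieved = "strict"), class = "vn_invariance")
  tab <- compare_factor_means(fake, "strict")
  expect_equal(tab$z[tab$factor == "metabolism"], 3.5)
  expect_lt(tab$p[tab$factor == "metabolism"], 0.001)
  expect_equal(tab$p[tab$factor == "salt"], 1)
  ## LCV-scale translation
  tab2 <- compare_factor_means(fake, "strict",
                               anchor_scale = c(metabolism = 0.115,
                                                salt = 0.107))
  expect_equal(tab2$estimate_lcv[tab2$factor == "metabolism"], 0.049 * 0.115)
  expect_error(compare_factor_means(fake, "metric"),
               class = "varnet_input_error")
  fake$achieved <- "metric"
  expect_error(compare_factor_means(fake, "strict"),
               class = "varnet_input_error")
})

test_that("a planted diabetic-style offset is detected with correct sign", {
  sp <- cohort_spec()
  ## double the F1 offset (0.10 on the LCV scale) for a power check
  g <- varnet:::default_groups()
  g$offset_lcv["diabetic", ] <- c(0.10, 0, 0, 0, 0, 0)
  sp2 <- cohort_spec(groups = g)
  hits <- logical(5)
  for (s in seq_along(hits)) {
    coh <- simulate_cohort(sp2, seed = 800 + s)
    L <- lcv_matrix(coh)
    gv <- coh$metadata$group[match(rownames(L), coh$metadata$patient_id)]
    fit <- cfa(default_cfa_model(), data = L,
               group = factor(gv, levels = c("non-diabetic", "diabetic")),
               level = "strict")
    sel <- grep("^alpha:metabolism", names(fit$estimates))
    z <- fit$estimates[sel] / fit$se[sel]
    hits[s] <- fit$estimates[sel] > 0 && 2 * pnorm(-abs(z)) < 0.05
  }
  expect_gte(mean(hits), 0.8)
})

test_that("partial invariance releases specific residuals", {
  L <- cached_lcv(2)
  set.seed(79)
  g <- sample(rep(c("g1", "g2"), length.out = nrow(L)))
  inv <- invariance_ladder(default_cfa_model(), L, g,
                           release = list(strict = c("Hb", "WBC", "Plat")))
  expect_equal(inv$grid$df[inv$grid$level == "strict"], 209)
  expect_equal(inv$deltas$delta_df[3], 13)  # 16 residuals - 3 released
})
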