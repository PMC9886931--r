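test_that("default six-domain model has the documented shape", {
  m <- default_cfa_model()
  expect_equal(length(m$factors), 6L)
  expect_equal(length(m$indicators), 16L)
  expect_equal(m$n_loadings, 18L)
  expect_true(all(c("Alb", "Hb") %in%
                    m$loadings$indicator[m$loadings$factor == "metabolism"]))
})

test_that("model degrees of freedom cover the single and multi-group ladder", {
  m <- default_cfa_model()
  expect_equal(model_df(m), 87L)
  expect_equal(model_df(m, mean_structure = TRUE), 87L)  # means add p and p
  expect_equal(model_df(m, 2, TRUE, "configural"), 174L)
  expect_equal(model_df(m, 2, TRUE, "metric"), 186L)
  expect_equal(model_df(m, 2, TRUE, "scalar"), 196L)
  expect_equal(model_df(m, 2, TRUE, "strict"), 212L)
  expect_equal(model_df("saturated"), 0L)
  ## releasing three strict residuals mirrors a partial-invariance fit
  expect_equal(model_df(m, 2, TRUE, "strict",
                        release = list(strict = c("Hb", "WBC", "Plat"))),
               209L)
})

test_that("declarative text configs round-trip through the parser", {
  d <- withr::local_tempdir()
  cfg <- file.path(d, "model.cfg")
  writeLines(c("# six domains", "metabolism: BUN Cr K",
               "salt: Na Cl", "cross: Hb metabolism",
               "kind: correlated-factors"), cfg)
  m <- read_cfa_model(cfg)
  expect_equal(m$factors, c("metabolism", "salt"))
  expect_equal(m$n_loadings, 6L)
  expect_true("Hb" %in% m$indicators)
})

test_that("one-factor fit matches the closed-form loading solution", {
  R <- diag(3)
  R[1, 2] <- R[2, 1] <- 0.35
  R[1, 3] <- R[3, 1] <- 0.42
  R[2, 3] <- R[3, 2] <- 0.30
  dimnames(R) <- list(c("a", "b", "c"), c("a", "b", "c"))
  fit <- cfa(cfa_model(list(F1 = c("a", "b", "c"))), sample.cov = R,
             n.obs = 200)
  expect_equal(unname(fit$params[[1]]$Lambda[, 1]), c(0.70, 0.50, 0.60),
               tolerance = 1e-4)
  expect_lt(abs(fit$statistic), 1e-6)
})

test_that("population moments from the model are recovered exactly", {
  m <- default_cfa_model()
  sp <- cohort_spec()
  ind <- m$indicators
  Lam0 <- matrix(0, 16, 6, dimnames = list(ind, m$factors))
  for (k in seq_len(nrow(m$loadings)))
    Lam0[m$loadings$indicator[k], m$loadings$factor[k]] <-
      sp$loadings_std[m$loadings$indicator[k], m$loadings$factor[k]]
  Phi0 <- sp$factor_corr
  Th0 <- pmax(1 - diag(Lam0 %*% Phi0 %*% t(Lam0)), 0.1)
  Sig0 <- Lam0 %*% Phi0 %*% t(Lam0) + diag(Th0)
  dimnames(Sig0) <- list(ind, ind)
  fit <- cfa(m, sample.cov = Sig0, n.obs = 334)
  expect_lt(abs(fit$statistic), 1e-6)
  expect_lt(max(abs(fit$params[[1]]$Lambda[, m$factors] - Lam0)), 1e-4)
  expect_lt(max(abs(fit$params[[1]]$Phi - Phi0)), 1e-4)
  expect_lt(max(abs(fit$params[[1]]$theta - Th0)), 1e-4)
  expect_lt(fit$grad_norm, 1e-4)
})

test_that("saturated fits return T = 0 with Sigma-hat equal to S", {
  L <- cached_lcv(1)[, 1:5]
  fit <- cfa("saturated", data = L)
  expect_identical(fit$statistic, 0)
  expect_identical(fit$df, 0L)
  S_ml <- cov(L) * (nrow(L) - 1) / nrow(L)
  expect_lt(max(abs(fit$params[[1]]$Sigma - S_ml)), 1e-8)
})

test_that("fit indices reproduce the printed RMSEA arithmetic", {
  fi1 <- fit_indices(147.6, 87, 3000, 120, 334)
  expect_equal(round(unname(fi1["RMSEA"]), 3), 0.046)
  fi2 <- fit_indices(178.8, 114, 3000, 231, 334)
  expect_equal(round(unname(fi2["RMSEA"]), 3), 0.041)
  ## clamping when T <= df
  fi3 <- fit_indices(80, 87, 3000, 120, 334)
  expect_equal(unname(fi3["CFI"]), 1)
  expect_equal(unname(fi3["RMSEA"]), 0)
  ## TLI undefined when the baseline ratio is 1
  fi4 <- fit_indices(10, 5, 20, 20, 100)
  expect_true(is.na(fi4["TLI"]))
})

test_that("information criteria follow their definitions", {
  ic0 <- information_criteria(-123.4, 0, 50)
  expect_equal(unname(ic0["AIC"]), 246.8)
  expect_equal(unname(ic0["BIC"]), 246.8)
  ic <- information_criteria(-100, 7, 334)
  expect_equal(unname(ic["BIC"] - ic["AIC"]), 7 * (log(334) - 2))
  ## nested models: AIC difference decomposes
  ic2 <- information_criteria(-95, 10, 334)
  expect_equal(unname(ic2["AIC"] - ic["AIC"]), 2 * (-95 - -100) * -1 + 2 * 3)
})

test_that("gradient at the optimum is numerically zero on data fits", {
  fit <- cfa(default_cfa_model(), data = cached_lcv(1), se = FALSE)
  expect_lt(fit$grad_norm, 1e-4)
  expect_true(fit$converged)
})

test_that("factor scores return the factor means at the model-implied mean", {
  fit <- cfa(default_cfa_model(), data = cached_lcv(1), se = FALSE)
  mu <- fit$mom[[1]]$xbar
  sc <- factor_scores(fit, matrix(mu, 1, dimnames = list(NULL, names(mu))))
  expect_lt(max(abs(sc - fit$params[[1]]$alpha)), 1e-10)
})

test_that("factor scores converge to the latent truth as noise vanishes", {
  set.seed(41)
  m2 <- cfa_model(list(A = c("x1", "x2", "x3"), B = c("y1", "y2", "y3")))
  n <- 400
  eta <- matrix(rnorm(n * 2), n, 2) %*% chol(matrix(c(1, .3, .3, 1), 2))
  lam <- c(0.9, 0.8, 0.7)
  X <- cbind(eta[, 1] %o% lam, eta[, 2] %o% lam) +
    matrix(rnorm(n * 6, 0, 1e-3), n, 6)
  colnames(X) <- c("x1", "x2", "x3", "y1", "y2", "y3")
  fit <- cfa(m2, data = X, se = FALSE)
  sc <- factor_scores(fit, X)
  expect_gt(abs(cor(sc[, "A"], eta[, 1])), 0.999)
  expect_gt(abs(cor(sc[, "B"], eta[, 2])), 0.999)
})

test_that("factor scores recover simulated domain scores on cohorts", {
  rs <- numeric(4)
  sp <- cohort_spec()
  for (s in 1:4) {
    coh <- simulate_cohort(sp, seed = 700 + s)
    L <- lcv_matrix(coh)
    fit <- cfa(default_cfa_model(), data = L, se = FALSE)
    sc <- factor_scores(fit, L)
    rs[s] <- cor(sc[, "metabolism"], coh$truth$eta[rownames(sc), "metabolism"])
  }
  expect_gt(mean(rs), 0.8)
})

test_that("second-order and bifactor variants reproduce their own truths", {
  ind <- default_cfa_model()$indicators
  m_so <- default_cfa_model(kind = "second-order")
  sp <- cohort_spec()
  Lam0 <- matrix(0, 16, 6, dimnames = list(ind, m_so$factors))
  for (k in seq_len(nrow(m_so$loadings)))
    Lam0[m_so$loadings$indicator[k], m_so$loadings$factor[k]] <-
      sp$loadings_std[m_so$loadings$indicator[k], m_so$loadings$factor[k]]
  g0 <- c(0.8, 0.6, 0.5, 0.55, 0.65, 0.7)
  Phi0 <- tcrossprod(g0) + diag(1 - g0^2)
  Th0 <- pmax(1 - diag(Lam0 %*% Phi0 %*% t(Lam0)), 0.1)
  Sig0 <- Lam0 %*% Phi0 %*% t(Lam0) + diag(Th0)
  dimnames(Sig0) <- list(ind, ind)
  fit_so <- cfa(m_so, sample.cov = Sig0, n.obs = 334)
  expect_lt(abs(fit_so$statistic), 1e-4)
  g_hat <- fit_so$estimates[grep("^psi_g:", names(fit_so$estimates))]
  fac <- sub("^psi_g:([^@]*)@?.*$", "\\1", names(g_hat))
  expect_lt(max(abs(abs(g_hat[match(m_so$factors, fac)]) - g0)), 1e-3)

  m_bi <- default_cfa_model(kind = "bifactor")
  Lam_b <- cbind(Lam0 * 0.6, general = rep(0.5, 16))
  Th_b <- pmax(1 - rowSums(Lam_b^2), 0.1)
  Sig_b <- Lam_b %*% t(Lam_b) + diag(Th_b)
  dimnames(Sig_b) <- list(ind, ind)
  fit_bi <- cfa(m_bi, sample.cov = Sig_b, n.obs = 334, se = FALSE)
  expect_lt(abs(fit_bi$statistic), 1e-4)
})

test_that("robust scaling factor is near 1 for normal data", {
  set.seed(43)
  L <- cached_lcv(1)
  fit <- cfa(default_cfa_model(), data = L, robust = TRUE, se = FALSE)
  expect_true(is.finite(fit$scaling_factor))
  expect_gt(fit$scaling_factor, 0.7)
  expect_lt(fit$scaling_factor, 1.4)
  expect_equal(fit$statistic_scaled, fit$statistic / fit$scaling_factor)
})

test_that("S3 methods expose the usual modelling surface", {
  fit <- cfa(default_cfa_model(), data = cached_lcv(1))
  expect_output(print(fit), "CFA fit")
  sm <- summary(fit)
  expect_true(all(c("estimate", "se", "z", "p") %in% names(sm$table)))
  expect_equal(length(coef(fit)), fit$n_free)
  ll <- logLik(fit)
  expect_equal(attr(ll, "df"), 49)
  expect_equal(unname(AIC(fit)), unname(fit$fit["AIC"]))
  res <- residuals(fit)[[1]]$cov
  expect_lt(max(abs(res)), 0.05 * max(diag(fit$mom[[1]]$S)) + 0.05)
  sc <- predict(fit, cached_lcv(1))
  expect_equal(dim(sc), c(334L, 6L))
})

test_that("the shipped model config reproduces the default model", {
  path <- system.file("extdata", "six-domain-model.cfg", package = "varnet")
  skip_if(path == "")
  m <- read_cfa_model(path)
  d <- default_cfa_model()
  expect_equal(m$factors, d$factors)
  expect_setequal(m$indicators, d$indicators)
  expect_equal(m$n_loadings, d$n_loadings)
  expect_equal(model_df(m), 87L)
})

test_that("simulate() draws reproduce the fitted moments", {
  fit <- cfa(default_cfa_model(), data = cached_lcv(1), se = FALSE)
  big <- simulate(fit, seed = 3)
  expect_equal(dim(big), c(334L, 16L))
  ## parametric bootstrap at larger n: refit statistic is central chi-square
  x <- simulate(fit, seed = 4)
  refit <- cfa(default_cfa_model(), data = x, se = FALSE)
  expect_lt(refit$statistic, qchisq(0.999, refit$df) * 2)
})
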