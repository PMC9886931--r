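test_that("EFA degrees of freedom follow the Lawley-Maxwell count", {
  expect_equal(efa_df(22, 6), 114L)
  expect_equal(efa_df(22, 5), 131L)
  expect_equal(efa_df(3, 1), 0L)
  expect_error(efa_df(5, 4), class = "varnet_spec_error")  # negative df
})

test_that("single-factor solution matches the closed form at df = 0", {
  R <- diag(3)
  R[1, 2] <- R[2, 1] <- 0.35
  R[1, 3] <- R[3, 1] <- 0.42
  R[2, 3] <- R[3, 2] <- 0.30
  fit <- efa(R, factors = 1, n.obs = 500)
  lam <- drop(fit$loadings)
  expect_equal(unname(lam), c(0.70, 0.50, 0.60), tolerance = 1e-4)
  expect_lt(fit$statistic, 1e-6)
  ## implied correlation reproduces S exactly when just-identified
  implied <- fit$loadings %*% t(fit$loadings) + diag(fit$uniquenesses)
  expect_lt(max(abs(implied - R)), 1e-5)
})

test_that("an identity correlation matrix yields null loadings", {
  R <- diag(6)
  dimnames(R) <- list(paste0("v", 1:6), paste0("v", 1:6))
  fit <- efa(R, factors = 1, n.obs = 200)
  expect_lt(max(abs(fit$loadings)), 1e-4)
  expect_true(all(fit$uniquenesses > 0.999))
})

test_that("ML solution agrees with factanal on a simulated panel", {
  L <- cached_lcv(1)
  R <- cor(L)
  ours <- efa(L, factors = 6, rotation = "none")
  ref <- factanal(covmat = R, factors = 6, n.obs = 334, rotation = "none")
  ## same profile optimum: uniquenesses and discrepancy value
  expect_lt(max(abs(ours$uniquenesses[names(ref$uniquenesses)] -
                      ref$uniquenesses)), 1e-3)
  expect_equal(ours$statistic / 333, ref$criteria[["objective"]],
               tolerance = 1e-4)
  expect_equal(ours$df, ref$dof)
})

test_that("oblimin rotation preserves communalities and fit", {
  L <- cached_lcv(1)
  fit <- efa(L, factors = 6, rotation = "oblimin")
  unrot <- rowSums(fit$loadings^2)
  rot_h2 <- diag(fit$pattern %*% fit$Phi %*% t(fit$pattern))
  expect_lt(max(abs(unrot - rot_h2)), 1e-8)
  ## the rotated solution implies the same correlation matrix (T unchanged)
  expect_lt(max(abs(fit$pattern %*% fit$Phi %*% t(fit$pattern) -
                      fit$loadings %*% t(fit$loadings))), 1e-8)
  expect_true(all(abs(diag(fit$Phi) - 1) < 1e-8))
  ## single factor: rotation is the identity
  f1 <- efa(L[, 1:5], factors = 1)
  expect_equal(f1$pattern, f1$loadings)
})

test_that("oblimin recovers a planted oblique simple structure", {
  lam <- matrix(0, 8, 2, dimnames = list(paste0("v", 1:8), c("A", "B")))
  lam[1:4, 1] <- c(0.8, 0.7, 0.6, 0.5)
  lam[5:8, 2] <- c(0.8, 0.7, 0.6, 0.5)
  phi <- matrix(c(1, 0.4, 0.4, 1), 2)
  R <- lam %*% phi %*% t(lam)
  diag(R) <- 1
  dimnames(R) <- list(paste0("v", 1:8), paste0("v", 1:8))
  fit <- efa(R, factors = 2, n.obs = 1000)
  perm <- match_factors(lam, fit$pattern)
  pat <- fit$pattern[, perm]
  pat <- sweep(pat, 2, sign(colSums(pat * lam)), `*`)
  expect_lt(max(abs(pat - lam)), 0.01)
  expect_lt(abs(abs(fit$Phi[1, 2]) - 0.4), 0.02)
})

test_that("variance explained is non-negative with non-decreasing cumulative", {
  fit <- efa(cached_lcv(1), factors = 6)
  expect_true(all(fit$variance_explained >= 0))
  expect_true(all(diff(fit$cumulative) >= 0))
  expect_true(all(diff(fit$variance_explained) <= 1e-8))  # sorted by size
})

test_that("Heywood uniquenesses are bounded and flagged", {
  lam <- c(0.995, 0.7, 0.6, 0.5)
  R <- tcrossprod(lam); diag(R) <- 1
  dimnames(R) <- list(paste0("v", 1:4), paste0("v", 1:4))
  fit <- efa(R, factors = 1, n.obs = 300)
  expect_true(all(fit$uniquenesses >= 0.005 - 1e-9))
})

test_that("parallel analysis nulls, single-factor and panel behavior", {
  ## pure noise: no factors suggested at a stringent quantile
  set.seed(31)
  sug0 <- vapply(1:30, function(i)
    parallel_analysis(matrix(rnorm(200 * 22), 200, 22), n_reps = 100,
                      quantile = 0.99, seed = i)$suggested, integer(1))
  expect_gte(mean(sug0 == 0), 0.9)
  ## one strong factor
  set.seed(32)
  eta <- rnorm(300)
  X <- sapply(1:6, function(j) 0.8 * eta + 0.6 * rnorm(300))
  pa1 <- parallel_analysis(X, n_reps = 100, seed = 1)
  expect_equal(pa1$suggested, 1L)
  ## simulated panel: suggestion in the plausible range, Kaiser close to 6
  pa <- parallel_analysis(cached_lcv(1), n_reps = 100, seed = 1)
  expect_true(pa$suggested >= 5 && pa$suggested <= 8)
  expect_true(pa$kaiser >= 4 && pa$kaiser <= 8)
})

test_that("bold simple structure is recovered from simulated cohorts", {
  sp <- cohort_spec()
  truth <- sp$loadings_std
  bold <- which(truth >= 0.4, arr.ind = TRUE)
  ok <- matrix(NA, 6, nrow(bold))
  for (s in 1:6) {
    L <- lcv_matrix(simulate_cohort(sp, seed = 600 + s))
    pat <- efa(L, factors = 6)$pattern
    perm <- match_factors(truth, pat)
    ok[s, ] <- vapply(seq_len(nrow(bold)), function(b) {
      v <- rownames(truth)[bold[b, 1]]
      which.max(abs(pat[v, ])) == perm[bold[b, 2]]
    }, logical(1))
  }
  ## every bold variable lands on its generating factor in >= 5 of 6 runs
  expect_true(all(colMeans(ok) >= 5 / 6))
})
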