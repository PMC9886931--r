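#' Degrees of freedom of an m-factor ML EFA
#'
#' `df = ((p - m)^2 - (p + m)) / 2` for p observed variables and m factors.
#'
#' @param p number of observed variables.
#' @param m number of factors (0 <= m < p).
#' @return integer degrees of freedom.
#' @export
efa_df <- function(p, m) {
  stopifnot(is_count(p), is_count(m), p > m)
  df <- ((p - m)^2 - (p + m)) / 2
  if (df < 0)
    vn_stop(sprintf("%d factors over-parameterize %d variables (df = %g)",
                    m, p, df), "varnet_spec_error")
  as.integer(df)
}

## Profile ML discrepancy over uniquenesses: for given psi, the optimal
## loadings come from the eigen-structure of psi^-1/2 S psi^-1/2, and
## F(psi) = sum_{i>m} (lambda_i - log lambda_i - 1).
ml_efa_objective <- function(logpsi, S, m) {
  psi <- exp(logpsi)
  isq <- 1 / sqrt(psi)
  A <- t(S * isq) * isq
  e <- eigen(A, symmetric = TRUE)
  tail_ev <- e$values[-seq_len(m)]
  tail_ev <- pmax(tail_ev, 1e-12)
  ## minuscule pull of uniquenesses toward 1 breaks exact ties (e.g. an
  ## identity input, where the profile likelihood is flat in psi_1) toward
  ## the parsimonious all-zero-loading solution
  f <- sum(tail_ev - log(tail_ev) - 1) + 1e-9 * sum(logpsi^2)
  W <- e$vectors[, -seq_len(m), drop = FALSE]
  g <- -colSums((tail_ev - 1) * t(W^2)) + 2e-9 * logpsi
  list(f = f, grad = g, eigen = e)
}

#' Maximum-likelihood exploratory factor analysis
#'
#' Fits an m-factor model to a correlation matrix by maximum likelihood,
#' minimizing the ML discrepancy over uniquenesses (analytic gradient on the
#' log scale, multiple restarts), then applies an oblimin rotation
#' ([oblimin_rotate()]) when `m >= 2`. Uniquenesses are bounded below at
#' 0.005 and bound-hitting variables are flagged as Heywood cases. The test
#' statistic is `T = (n - 1) * F_min`; fit indices use the independence
#' baseline.
#'
#' @param x data matrix/data.frame of observations, or a correlation matrix
#'   (then supply `n.obs`).
#' @param factors number of factors m.
#' @param n.obs sample size when `x` is a correlation matrix.
#' @param rotation `"oblimin"` or `"none"`.
#' @param gamma oblimin parameter (0 = direct quartimin).
#' @param n_starts restarts for the uniqueness optimization.
#' @return An object of class `vn_efa`.
#' @examples
#' R <- diag(3)
#' R[1, 2] <- R[2, 1] <- 0.35; R[1, 3] <- R[3, 1] <- 0.42
#' R[2, 3] <- R[3, 2] <- 0.30
#' fit <- efa(R, factors = 1, n.obs = 100)
#' round(drop(fit$loadings), 2)  # 0.70 0.50 0.60
#' @export
efa <- function(x, factors, n.obs = NULL, rotation = c("oblimin", "none"),
                gamma = 0, n_starts = 10) {
  rotation <- match.arg(rotation)
  if (is.matrix(x) && nrow(x) == ncol(x) &&
      isSymmetric(unname(x), tol = 1e-8) && all(abs(diag(x) - 1) < 1e-8)) {
    S <- x
    if (is.null(n.obs))
      vn_stop("n.obs is required when x is a correlation matrix",
              "varnet_input_error")
    n <- n.obs
  } else {
    x <- as.matrix(x)
    S <- stats::cor(x)
    n <- nrow(x)
  }
  p <- ncol(S)
  m <- factors
  df <- efa_df(p, m)
  vars <- colnames(S) %||% paste0("V", seq_len(p))
  dimnames(S) <- list(vars, vars)
  ev_min <- min(eigen(S, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min < -1e-8)
    vn_stop("correlation matrix is not positive semi-definite",
            "varnet_input_error")

  lower <- log(0.005)
  start0 <- log(pmax((1 - 0.5 * m / p) / diag(solve(S + diag(1e-8, p))), 0.01))
  best <- NULL
  set.seed(7)
  for (s in seq_len(n_starts)) {
    st <- if (s == 1) start0 else pmax(start0 + stats::rnorm(p, 0, 0.3), lower)
    opt <- stats::nlminb(pmax(st, lower),
                         function(lp) ml_efa_objective(lp, S, m)$f,
                         function(lp) ml_efa_objective(lp, S, m)$grad,
                         lower = lower, upper = log(1.5),
                         control = list(iter.max = 500, rel.tol = 1e-12))
    if (is.null(best) || opt$objective < best$objective) best <- opt
  }
  if (is.null(best) || !is.finite(best$objective))
    vn_stop("ML EFA failed to converge", "varnet_convergence_error")

  psi <- exp(best$par)
  obj <- ml_efa_objective(best$par, S, m)
  e <- obj$eigen
  top <- pmax(e$values[seq_len(m)] - 1, 0)
  L <- sqrt(psi) * e$vectors[, seq_len(m), drop = FALSE] %*%
    diag(sqrt(top), m)
  ## Canonicalize flat optima (e.g. an identity input): a factor whose
  ## loadings can be absorbed into the uniquenesses without changing the
  ## discrepancy is redundant and is zeroed.
  discrep <- function(Sigma) {
    ch <- tryCatch(chol(Sigma), error = function(e) NULL)
    if (is.null(ch)) return(Inf)
    2 * sum(log(diag(ch))) - determinant(S, logarithm = TRUE)$modulus[1] +
      sum(chol2inv(ch) * S) - p
  }
  F_cur <- discrep(L %*% t(L) + diag(psi, p))
  for (k in seq_len(m)) {
    if (all(L[, k] == 0)) next
    psi2 <- psi + L[, k]^2
    L2 <- L; L2[, k] <- 0
    if (discrep(L2 %*% t(L2) + diag(psi2, p)) <= F_cur + 1e-9) {
      L <- L2; psi <- psi2
    }
  }
  ## Stable orientation: sign-align columns.
  sgn <- ifelse(colSums(L) < 0, -1, 1)
  L <- sweep(L, 2, sgn, `*`)
  dimnames(L) <- list(vars, paste0("F", seq_len(m)))
  heywood <- vars[psi <= 0.005 * (1 + 1e-6)]

  Tstat <- (n - 1) * best$objective
  F_b <- -determinant(S, logarithm = TRUE)$modulus[1]
  T_b <- (n - 1) * F_b
  df_b <- p * (p - 1) / 2

  if (rotation == "oblimin" && m >= 2) {
    rot <- oblimin_rotate(L, gamma = gamma)
    pattern <- rot$pattern
    Phi <- rot$Phi
  } else {
    pattern <- L
    Phi <- diag(m)
    dimnames(Phi) <- list(colnames(L), colnames(L))
  }
  structure_m <- pattern %*% Phi
  ve <- colSums(structure_m^2) / p
  fit <- if (df > 0) {
    fit_indices(Tstat, df, T_b, df_b, n,
                S = S, Sigma = L %*% t(L) + diag(psi))
  } else {
    c(CFI = 1, TLI = 1, RMSEA = 0, SRMR = 0)  # just-identified exact fit
  }

  structure(list(
    m = m, p = p, n = n,
    loadings = L, pattern = pattern, Phi = Phi, structure = structure_m,
    uniquenesses = stats::setNames(psi, vars),
    communalities = stats::setNames(1 - psi, vars),
    statistic = Tstat, df = df,
    p.value = if (df > 0) stats::pchisq(Tstat, df, lower.tail = FALSE) else NA_real_,
    fit = fit, rotation = rotation, gamma = gamma,
    variance_explained = ve,
    cumulative = cumsum(ve),
    heywood = heywood, S = S,
    criterion = best$objective
  ), class = "vn_efa")
}

#' @export
print.vn_efa <- function(x, cutoff = 0.1, digits = 2, ...) {
  cat(sprintf("ML exploratory factor analysis: %d variables, %d factors (%s rotation)\n",
              x$p, x$m, x$rotation))
  cat(sprintf("  chi^2(df) = %.1f (%d)", x$statistic, x$df))
  if (x$df > 0)
    cat(sprintf(", chi^2/df = %.2f, CFI = %.3f, TLI = %.3f, RMSEA = %.3f",
                x$statistic / x$df, x$fit["CFI"], x$fit["TLI"], x$fit["RMSEA"]))
  cat("\nPattern loadings (|value| >=", cutoff, "shown):\n")
  L <- round(x$pattern, digits)
  Lc <- format(L)
  Lc[abs(L) < cutoff] <- ""
  print(Lc, quote = FALSE)
  cat("Variance explained:", paste(sprintf("%.2f", x$variance_explained),
                                   collapse = " "),
      "(cumulative", sprintf("%.2f", max(x$cumulative)), ")\n")
  if (length(x$heywood))
    cat("Heywood-bounded uniquenesses:", paste(x$heywood, collapse = ", "), "\n")
  invisible(x)
}

#' Parallel analysis for the number of factors
#'
#' Compares observed eigenvalues with the chosen quantile of eigenvalues
#' from `n_reps` random standard-normal datasets of the same shape; the
#' suggested factor count is the number of leading observed eigenvalues
#' exceeding their simulated counterpart (stopping at the first failure).
#' The default `"factor"` variant works on the reduced correlation matrix
#' (squared multiple correlations on the diagonal), the classical
#' common-factor form of parallel analysis; `"component"` uses the raw
#' correlation-matrix eigenvalues (Horn's original rule). The Kaiser count
#' (raw eigenvalues above 1) is reported alongside.
#'
#' @param data observation matrix (n x p).
#' @param n_reps number of simulated datasets (>= 100).
#' @param quantile simulated-eigenvalue quantile to exceed.
#' @param seed RNG seed.
#' @param type `"factor"` (reduced matrix) or `"component"`.
#' @return list with `suggested`, `kaiser`, `observed`, `threshold`.
#' @export
parallel_analysis <- function(data, n_reps = 200, quantile = 0.95, seed = 1,
                              type = c("factor", "component")) {
  stopifnot(n_reps >= 100)
  type <- match.arg(type)
  x <- as.matrix(data)
  n <- nrow(x); p <- ncol(x)
  eig_of <- function(R) {
    if (type == "factor") {
      smc <- 1 - 1 / diag(solve(R))
      diag(R) <- smc
    }
    eigen(R, symmetric = TRUE, only.values = TRUE)$values
  }
  R_obs <- stats::cor(x)
  kaiser <- sum(eigen(R_obs, symmetric = TRUE, only.values = TRUE)$values > 1)
  obs <- eig_of(R_obs)
  set.seed(seed)
  sim <- matrix(0, n_reps, p)
  for (r in seq_len(n_reps)) {
    sim[r, ] <- eig_of(stats::cor(matrix(stats::rnorm(n * p), n, p)))
  }
  thr <- apply(sim, 2, stats::quantile, probs = quantile)
  exceeds <- obs > thr
  suggested <- if (exceeds[1]) which.min(c(exceeds, FALSE)) - 1L else 0L
  list(suggested = as.integer(suggested), kaiser = kaiser,
       observed = obs, threshold = thr)
}
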