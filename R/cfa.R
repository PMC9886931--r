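# Confirmatory factor analysis engine: normal-theory ML with mean structure,
# equality constraints via shared parameter labels, analytic gradients.

## Per-group index maps from a parameter table.
make_maps <- function(ptab, model, n_groups) {
  factors_all <- model$factors
  if (model$kind == "bifactor") factors_all <- c(factors_all, "general")
  p <- length(model$indicators); M <- length(factors_all)
  maps <- vector("list", n_groups)
  for (g in seq_len(n_groups)) {
    pt <- ptab[ptab$group == g, ]
    Lidx <- matrix(0L, p, M, dimnames = list(model$indicators, factors_all))
    sel <- pt$mat == "lambda"
    Lidx[cbind(match(pt$row[sel], model$indicators),
               match(pt$col[sel], factors_all))] <- pt$par_id[sel]
    phi_off <- matrix(0L, M, M, dimnames = list(factors_all, factors_all))
    sel <- pt$mat == "phi" & pt$row != pt$col
    if (any(sel))
      phi_off[cbind(match(pt$row[sel], factors_all),
                    match(pt$col[sel], factors_all))] <- pt$par_id[sel]
    phi_diag <- integer(M)
    sel <- pt$mat == "phi" & pt$row == pt$col
    if (any(sel)) phi_diag[match(pt$row[sel], factors_all)] <- pt$par_id[sel]
    psi_g <- integer(M)
    sel <- pt$mat == "psi_g"
    if (any(sel)) psi_g[match(pt$row[sel], factors_all)] <- pt$par_id[sel]
    theta <- integer(p)
    sel <- pt$mat == "theta"
    theta[match(pt$row[sel], model$indicators)] <- pt$par_id[sel]
    nu <- integer(p)
    sel <- pt$mat == "nu"
    if (any(sel)) nu[match(pt$row[sel], model$indicators)] <- pt$par_id[sel]
    alpha <- integer(M)
    sel <- pt$mat == "alpha"
    if (any(sel)) alpha[match(pt$row[sel], factors_all)] <- pt$par_id[sel]
    maps[[g]] <- list(Lidx = Lidx, phi_off = phi_off, phi_diag = phi_diag,
                      psi_g = psi_g, theta = theta, nu = nu, alpha = alpha)
  }
  list(groups = maps, factors = factors_all, indicators = model$indicators,
       kind = model$kind, p = p, M = M)
}

assemble_group <- function(x, mp, kind) {
  M <- length(mp$phi_diag); p <- length(mp$theta)
  Lambda <- matrix(0, p, M, dimnames = dimnames(mp$Lidx))
  Lambda[mp$Lidx > 0] <- x[mp$Lidx[mp$Lidx > 0]]
  if (kind == "second-order") {
    gvec <- numeric(M)
    gvec[mp$psi_g > 0] <- x[mp$psi_g[mp$psi_g > 0]]
    Phi <- tcrossprod(gvec) + diag(pmax(1 - gvec^2, 1e-8), M)
  } else if (kind == "bifactor") {
    Phi <- diag(M); gvec <- NULL
  } else {
    Phi <- matrix(0, M, M)
    Phi[mp$phi_off > 0] <- x[mp$phi_off[mp$phi_off > 0]]
    Phi <- Phi + t(Phi)
    dg <- rep(1, M)
    dg[mp$phi_diag > 0] <- x[mp$phi_diag[mp$phi_diag > 0]]
    diag(Phi) <- dg
    gvec <- NULL
  }
  dimnames(Phi) <- dimnames(mp$Lidx)[c(2, 2)]
  theta <- exp(x[mp$theta])   # residual variances live on the log scale
  nu <- numeric(p); nu[mp$nu > 0] <- x[mp$nu[mp$nu > 0]]
  alpha <- numeric(M); alpha[mp$alpha > 0] <- x[mp$alpha[mp$alpha > 0]]
  list(Lambda = Lambda, Phi = Phi, theta = theta, nu = nu, alpha = alpha,
       gvec = gvec)
}

## Weighted ML discrepancy and gradient over all groups.
## f = sum_g (n_g - 1) * [ln|Sigma| - ln|S_g| + tr(S_g Sigma^-1) - p + d'Sigma^-1 d]
cfa_objective <- function(x, maps, mom, mean_structure, want_grad = FALSE) {
  f <- 0
  grad <- if (want_grad) numeric(length(x)) else NULL
  p <- maps$p
  for (g in seq_along(maps$groups)) {
    mp <- maps$groups[[g]]
    par <- assemble_group(x, mp, maps$kind)
    LP <- par$Lambda %*% par$Phi
    Sigma <- LP %*% t(par$Lambda)
    diag(Sigma) <- diag(Sigma) + par$theta
    ch <- tryCatch(chol(Sigma), error = function(e) NULL)
    if (is.null(ch))
      return(list(f = 1e10 + sum(x^2), grad = if (want_grad) 2 * x else NULL))
    Sinv <- chol2inv(ch)
    S <- mom[[g]]$S
    w <- mom[[g]]$n - 1
    Fg <- 2 * sum(log(diag(ch))) - mom[[g]]$logdetS + sum(Sinv * S) - p
    d <- NULL
    if (mean_structure) {
      d <- mom[[g]]$xbar - (par$nu + drop(par$Lambda %*% par$alpha))
      Fg <- Fg + drop(crossprod(d, Sinv %*% d))
    }
    f <- f + w * Fg
    if (want_grad) {
      Resid <- Sigma - S
      if (mean_structure) Resid <- Resid - tcrossprod(d)
      G <- Sinv %*% Resid %*% Sinv
      dL <- 2 * G %*% LP
      H <- crossprod(par$Lambda, G) %*% par$Lambda
      u <- NULL
      if (mean_structure) {
        u <- -2 * drop(Sinv %*% d)
        dL <- dL + tcrossprod(u, par$alpha)
      }
      idx <- mp$Lidx > 0
      grad_add <- function(ids, vals) {
        for (k in seq_along(ids)) grad[ids[k]] <<- grad[ids[k]] + w * vals[k]
      }
      grad_add(mp$Lidx[idx], dL[idx])
      if (maps$kind == "correlated-factors") {
        idx <- mp$phi_off > 0
        if (any(idx)) grad_add(mp$phi_off[idx], 2 * H[idx])
        idx <- mp$phi_diag > 0
        if (any(idx)) grad_add(mp$phi_diag[idx], diag(H)[idx])
      } else if (maps$kind == "second-order") {
        gv <- par$gvec
        dg <- 2 * (drop(H %*% gv) - diag(H) * gv)
        idx <- mp$psi_g > 0
        grad_add(mp$psi_g[idx], dg[idx])
      }
      grad_add(mp$theta, diag(G) * par$theta)
      if (mean_structure) {
        idx <- mp$nu > 0
        if (any(idx)) grad_add(mp$nu[idx], u[idx])
        idx <- mp$alpha > 0
        if (any(idx)) grad_add(mp$alpha[idx], drop(crossprod(par$Lambda, u))[idx])
      }
    }
  }
  list(f = f, grad = grad)
}

## Start values and box bounds per free parameter.
cfa_starts <- function(ptab, mom, maps, warm = NULL) {
  n_free <- attr(ptab, "n_free")
  start <- numeric(n_free); lower <- rep(-Inf, n_free); upper <- rep(Inf, n_free)
  pooled_sd <- sqrt(Reduce(`+`, lapply(mom, function(m) diag(m$S) * (m$n - 1))) /
                      sum(vapply(mom, function(m) m$n - 1, 0)))
  names(pooled_sd) <- maps$indicators
  pooled_mean <- Reduce(`+`, lapply(mom, function(m) m$xbar * m$n)) /
    sum(vapply(mom, function(m) m$n, 0))
  names(pooled_mean) <- maps$indicators
  seen <- logical(n_free)
  for (k in seq_len(nrow(ptab))) {
    if (!ptab$free[k]) next
    id <- ptab$par_id[k]
    if (seen[id]) next
    seen[id] <- TRUE
    v <- ptab$row[k]
    start[id] <- switch(ptab$mat[k],
      lambda = 0.5 * pooled_sd[v],
      phi = if (ptab$row[k] == ptab$col[k]) 1 else 0,
      psi_g = 0.5,
      theta = log(0.5 * pooled_sd[v]^2),
      nu = pooled_mean[v],
      alpha = 0)
    if (ptab$mat[k] == "theta") {
      lower[id] <- log(pooled_sd[v]^2) + log(1e-5)
      upper[id] <- log(pooled_sd[v]^2) + log(100)
    }
    if (ptab$mat[k] == "phi" && ptab$row[k] == ptab$col[k]) lower[id] <- 1e-6
    if (ptab$mat[k] == "psi_g") { lower[id] <- -0.995; upper[id] <- 0.995 }
  }
  if (!is.null(warm)) {
    base <- sub("@g[0-9]+$", "", ptab$label)
    wbase <- sub("@g[0-9]+$", "", names(warm))
    for (id in seq_len(n_free)) {
      b <- base[match(id, ptab$par_id)]
      hit <- which(wbase == b)
      if (length(hit)) {
        v <- mean(warm[hit])
        if (startsWith(b, "theta:")) v <- log(max(v, 1e-12))
        start[id] <- v
      }
    }
    start <- pmin(pmax(start, lower + 1e-10), upper - 1e-10)
  }
  list(start = start, lower = lower, upper = upper)
}

#' Fit a confirmatory factor model
#'
#' Normal-theory maximum likelihood with optional mean structure and
#' multi-group equality constraints. The discrepancy
#' `F = ln|Sigma| - ln|S| + tr(S Sigma^-1) - p (+ (xbar - mu)' Sigma^-1 (xbar - mu))`
#' is minimized by a quasi-Newton method with analytic gradients; the test
#' statistic is `T = sum_g (n_g - 1) F_g` (Wishart convention). Standard
#' errors come from the inverse of the numerically evaluated information
#' matrix. Identification is by unit factor variances and zero factor means
#' in the reference configuration; invariance `level` controls which
#' parameters are constrained equal across groups (see
#' [invariance_ladder()]).
#'
#' @param model a [cfa_model()], or `"saturated"` for the saturated model.
#' @param data matrix/data.frame of indicator observations (columns must
#'   include the model's indicators). Alternatively supply moments.
#' @param group optional factor/character vector (length nrow(data)) for
#'   multi-group fits; its levels order the groups.
#' @param sample.cov,sample.mean,n.obs sample moments instead of raw data
#'   (lists for multiple groups). `sample.cov` uses the n - 1 divisor.
#' @param mean_structure fit intercepts and factor means; default `TRUE` for
#'   multi-group fits or when means are supplied.
#' @param level invariance level for multi-group fits.
#' @param release named list of per-level constraint exemptions (partial
#'   invariance), e.g. `list(strict = c("Hb"))`.
#' @param robust also compute a mean-scaled (Satorra-Bentler-style) test
#'   statistic from fourth moments (raw single-group data only).
#' @param se compute standard errors.
#' @param warm_start a previous `vn_cfa` fit used to initialize parameters.
#' @return An object of class `vn_cfa`.
#' @export
cfa <- function(model, data = NULL, group = NULL,
                sample.cov = NULL, sample.mean = NULL, n.obs = NULL,
                mean_structure = NULL, level = "configural",
                release = NULL, robust = FALSE, se = TRUE,
                warm_start = NULL) {
  ## --- Moments ---
  raw_groups <- NULL
  if (!is.null(data)) {
    data <- as.matrix(data)
    if (!identical(model, "saturated")) {
      miss <- setdiff(model$indicators, colnames(data))
      if (length(miss))
        vn_stop(sprintf("data lacks indicator(s): %s",
                        paste(miss, collapse = ", ")), "varnet_input_error")
      data <- data[, model$indicators, drop = FALSE]
    }
    if (anyNA(data))
      vn_stop("complete data required", "varnet_input_error")
    gf <- if (is.null(group)) factor(rep(1, nrow(data))) else factor(group)
    raw_groups <- lapply(levels(gf), function(l) data[gf == l, , drop = FALSE])
    names(raw_groups) <- levels(gf)
    mom <- lapply(raw_groups, function(xg) {
      list(S = stats::cov(xg), xbar = colMeans(xg), n = nrow(xg))
    })
  } else {
    if (is.null(sample.cov) || is.null(n.obs))
      vn_stop("supply data, or sample.cov with n.obs", "varnet_input_error")
    if (!is.list(sample.cov)) sample.cov <- list(sample.cov)
    if (!is.null(sample.mean) && !is.list(sample.mean))
      sample.mean <- list(sample.mean)
    mom <- lapply(seq_along(sample.cov), function(g) {
      list(S = as.matrix(sample.cov[[g]]),
           xbar = if (is.null(sample.mean)) rep(0, ncol(sample.cov[[g]]))
                  else sample.mean[[g]],
           n = n.obs[g])
    })
    names(mom) <- names(sample.cov) %||% paste0("g", seq_along(mom))
  }
  n_groups <- length(mom)
  if (is.null(mean_structure))
    mean_structure <- n_groups > 1 || !is.null(sample.mean)
  for (g in seq_along(mom))
    mom[[g]]$logdetS <- determinant(mom[[g]]$S, logarithm = TRUE)$modulus[1]
  n_total <- sum(vapply(mom, function(m) m$n, 0))

  ## --- Saturated model: closed form ---
  if (identical(model, "saturated")) {
    p <- ncol(mom[[1]]$S)
    loglik <- sum(vapply(mom, function(m) {
      S_ml <- m$S * (m$n - 1) / m$n
      -(m$n / 2) * (p * log(2 * pi) +
                      determinant(S_ml, logarithm = TRUE)$modulus[1] + p)
    }, 0))
    return(structure(list(model = "saturated", statistic = 0, df = 0L,
                          p.value = NA_real_, loglik = loglik,
                          n_free = n_groups * (p * (p + 1) / 2 +
                                                 if (mean_structure) p else 0),
                          params = lapply(mom, function(m)
                            list(Sigma = m$S * (m$n - 1) / m$n, mu = m$xbar)),
                          n = vapply(mom, function(m) m$n, 0),
                          converged = TRUE, mean_structure = mean_structure),
                     class = "vn_cfa"))
  }

  if (!is.null(colnames(mom[[1]]$S)) &&
      !identical(colnames(mom[[1]]$S), model$indicators)) {
    miss <- setdiff(model$indicators, colnames(mom[[1]]$S))
    if (length(miss))
      vn_stop(sprintf("moments lack indicator(s): %s",
                      paste(miss, collapse = ", ")), "varnet_input_error")
    for (g in seq_along(mom)) {
      idx <- match(model$indicators, colnames(mom[[g]]$S))
      mom[[g]]$S <- mom[[g]]$S[idx, idx]
      mom[[g]]$xbar <- mom[[g]]$xbar[idx]
      mom[[g]]$logdetS <- determinant(mom[[g]]$S, logarithm = TRUE)$modulus[1]
    }
  }

  ## --- Parameterization and optimization ---
  ptab <- build_ptab(model, n_groups, mean_structure, level, release)
  maps <- make_maps(ptab, model, n_groups)
  warm <- if (!is.null(warm_start) && inherits(warm_start, "vn_cfa"))
    warm_start$estimates else NULL
  sv <- cfa_starts(ptab, mom, maps, warm = warm)
  fn <- function(x) cfa_objective(x, maps, mom, mean_structure)$f
  gr <- function(x) cfa_objective(x, maps, mom, mean_structure, TRUE)$grad
  opt <- stats::nlminb(sv$start, fn, gr, lower = sv$lower, upper = sv$upper,
                       control = list(iter.max = 2000, eval.max = 4000,
                                      rel.tol = 1e-12))
  gnorm_of <- function(z) max(abs(gr(z))) / max(n_total - n_groups, 1)
  at_bound <- function(z) z <= sv$lower + 1e-9 | z >= sv$upper - 1e-9
  for (round in 1:3) {
    free_ok <- !at_bound(opt$par)
    if (max(abs(gr(opt$par))[free_ok]) / max(n_total - n_groups, 1) < 1e-5)
      break
    ## alternate quasi-Newton polishers; nlminb can stall short of the optimum
    opt2 <- stats::optim(opt$par, fn, gr, method = "L-BFGS-B",
                         lower = sv$lower, upper = sv$upper,
                         control = list(factr = 10, maxit = 5000))
    if (opt2$value < opt$objective)
      opt <- list(par = opt2$par, objective = opt2$value, convergence = 0)
    opt3 <- stats::nlminb(opt$par, fn, gr, lower = sv$lower, upper = sv$upper,
                          control = list(iter.max = 2000, eval.max = 4000,
                                         rel.tol = 1e-14))
    if (opt3$objective < opt$objective) opt <- opt3
  }
  ## Newton refinement on interior coordinates for the last mile.
  free_ok <- !at_bound(opt$par)
  if (max(abs(gr(opt$par))[free_ok]) / max(n_total - n_groups, 1) >= 1e-5) {
    for (nr in 1:5) {
      z <- opt$par
      act <- which(!at_bound(z))
      gv <- gr(z)
      if (max(abs(gv[act])) / max(n_total - n_groups, 1) < 1e-6) break
      H <- tryCatch(stats::optimHess(z, fn, gr), error = function(e) NULL)
      if (is.null(H)) break
      step <- tryCatch(solve(H[act, act] + diag(1e-8, length(act)), gv[act]),
                       error = function(e) NULL)
      if (is.null(step)) break
      improved <- FALSE
      for (damp in c(1, 0.5, 0.25, 0.1)) {
        z2 <- z
        z2[act] <- z[act] - damp * step
        z2 <- pmin(pmax(z2, sv$lower), sv$upper)
        f2 <- fn(z2)
        if (f2 < opt$objective) {
          opt <- list(par = z2, objective = f2, convergence = 0)
          improved <- TRUE
          break
        }
      }
      if (!improved) break
    }
  }
  x <- opt$par
  free_ok <- !at_bound(x)
  gnorm <- max(abs(gr(x))[free_ok]) / max(n_total - n_groups, 1)
  converged <- is.finite(opt$objective) && opt$objective < 1e9 &&
    (opt$convergence == 0 || gnorm < 1e-4)
  if (!converged)
    vn_stop(sprintf("CFA did not converge (scaled gradient sup-norm %.2e)",
                    gnorm), "varnet_convergence_error")

  ## Canonical factor orientation: flip any factor whose group-1 loading
  ## column sums negative (sign indeterminacy of the latent scale).
  pr1 <- assemble_group(x, maps$groups[[1]], maps$kind)
  flip <- colnames(pr1$Lambda)[colSums(pr1$Lambda) < 0]
  if (length(flip)) {
    mult <- rep(1, length(x))
    for (k in seq_len(nrow(ptab))) {
      if (!ptab$free[k]) next
      mfl <- switch(ptab$mat[k],
        lambda = (-1)^(ptab$col[k] %in% flip),
        phi = (-1)^(ptab$row[k] %in% flip) * (-1)^(ptab$col[k] %in% flip),
        psi_g = (-1)^(ptab$row[k] %in% flip),
        alpha = (-1)^(ptab$row[k] %in% flip),
        1)
      mult[ptab$par_id[k]] <- mfl
    }
    x <- x * mult
  }

  free_labels <- unique(ptab$label[ptab$free])
  is_log <- startsWith(free_labels, "theta:")
  x_nat <- ifelse(is_log, exp(x), x)
  estimates <- stats::setNames(x_nat, free_labels)
  ptab$value <- ifelse(ptab$free, x_nat[ptab$par_id], ptab$value)
  params <- lapply(seq_len(n_groups), function(g) {
    pr <- assemble_group(x, maps$groups[[g]], maps$kind)
    Sigma <- pr$Lambda %*% pr$Phi %*% t(pr$Lambda)
    diag(Sigma) <- diag(Sigma) + pr$theta
    mu <- pr$nu + drop(pr$Lambda %*% pr$alpha)
    names(pr$theta) <- names(mu) <- maps$indicators
    names(pr$alpha) <- maps$factors
    list(Lambda = pr$Lambda, Phi = pr$Phi,
         theta = pr$theta, nu = stats::setNames(pr$nu, maps$indicators),
         alpha = pr$alpha, Sigma = Sigma, mu = mu)
  })
  names(params) <- names(mom)

  Tstat <- opt$objective
  df <- model_df(model, n_groups, mean_structure, level, release)

  ## Baseline (independence) model: diagonal Sigma, saturated means.
  p <- maps$p
  T_b <- sum(vapply(mom, function(m)
    (m$n - 1) * (sum(log(diag(m$S))) - m$logdetS), 0))
  df_b <- n_groups * p * (p - 1) / 2
  fit <- fit_indices(Tstat, max(df, 1), T_b, df_b, n_total,
                     S = lapply(mom, `[[`, "S"),
                     Sigma = lapply(params, `[[`, "Sigma"),
                     n_groups = n_groups)
  if (df == 0) fit[c("CFI", "TLI", "RMSEA")] <- c(1, 1, 0)

  loglik <- sum(vapply(seq_along(mom), function(g) {
    m <- mom[[g]]; S_ml <- m$S * (m$n - 1) / m$n
    Sg <- params[[g]]$Sigma
    ch <- chol(Sg); Sinv <- chol2inv(ch)
    d <- if (mean_structure) m$xbar - params[[g]]$mu else rep(0, p)
    -(m$n / 2) * (p * log(2 * pi) + 2 * sum(log(diag(ch))) +
                    sum(Sinv * S_ml) + drop(crossprod(d, Sinv %*% d)))
  }, 0))
  ic <- information_criteria(loglik, attr(ptab, "n_free"), n_total)

  ## Standard errors from the numerical information matrix.
  se_vec <- rep(NA_real_, length(x))
  vcov_m <- NULL
  if (se) {
    H <- tryCatch(stats::optimHess(x, function(z) fn(z) / 2,
                                   function(z) gr(z) / 2),
                  error = function(e) NULL)
    if (!is.null(H)) {
      vcov_m <- tryCatch(solve(H), error = function(e) NULL)
      if (!is.null(vcov_m)) {
        dv <- diag(vcov_m)
        se_vec <- ifelse(dv > 0, sqrt(pmax(dv, 0)), NA_real_)
        se_vec[is_log] <- se_vec[is_log] * exp(x[is_log])
      }
    }
    if (anyNA(se_vec))
      warning("information matrix not positive definite; some SEs are NA",
              call. = FALSE)
  }

  scaling <- NULL
  if (robust) {
    if (is.null(raw_groups) || n_groups > 1) {
      warning("robust scaling needs raw single-group data; plain ML reported",
              call. = FALSE)
    } else {
      cval <- sb_scaling(raw_groups[[1]], maps, mom, x, mean_structure, df)
      scaling <- list(c = cval, T_scaled = Tstat / cval)
    }
  }

  structure(list(
    model = model, level = if (n_groups > 1) level else NA_character_,
    ptab = ptab, maps = maps, estimates = estimates, se = se_vec,
    vcov = vcov_m, params = params,
    statistic = Tstat, df = df,
    p.value = if (df > 0) stats::pchisq(Tstat, df, lower.tail = FALSE) else NA_real_,
    scaling_factor = scaling$c %||% NA_real_,
    statistic_scaled = scaling$T_scaled %||% NA_real_,
    baseline = c(statistic = T_b, df = df_b),
    fit = c(fit, ic), loglik = loglik, n_free = attr(ptab, "n_free"),
    n = vapply(mom, function(m) m$n, 0), mom = mom,
    mean_structure = mean_structure, converged = converged,
    grad_norm = gnorm
  ), class = "vn_cfa")
}

#' @rdname cfa
#' @export
fit_cfa <- cfa

## Satorra-Bentler mean-scaled correction: c = tr(U Gamma) / df with
## U = W - W Delta (Delta' W Delta)^-1 Delta' W, Gamma the empirical
## fourth-moment covariance of the sample moments, W the normal-theory
## weight matrix; T_scaled = T / c.
sb_scaling <- function(xraw, maps, mom, x, mean_structure, df) {
  if (df <= 0) return(NA_real_)
  p <- maps$p; n <- nrow(xraw)
  xc <- sweep(xraw, 2, colMeans(xraw))
  lt <- which(lower.tri(matrix(0, p, p), diag = TRUE))
  scores <- t(apply(xc, 1, function(z) tcrossprod(z)[lt]))
  smat <- if (mean_structure) cbind(xraw, scores) else scores
  Gamma <- stats::cov(smat) * (n - 1) / n
  Sigma <- {
    pr <- assemble_group(x, maps$groups[[1]], maps$kind)
    S <- pr$Lambda %*% pr$Phi %*% t(pr$Lambda); diag(S) <- diag(S) + pr$theta
    S
  }
  Sinv <- solve(Sigma)
  Dup <- duplication_matrix(p)
  W_cov <- 0.5 * t(Dup) %*% (Sinv %x% Sinv) %*% Dup
  W <- if (mean_structure) {
    rbind(cbind(Sinv, matrix(0, p, nrow(W_cov))),
          cbind(matrix(0, nrow(W_cov), p), W_cov))
  } else W_cov
  mom_of <- function(z) {
    pr <- assemble_group(z, maps$groups[[1]], maps$kind)
    S <- pr$Lambda %*% pr$Phi %*% t(pr$Lambda); diag(S) <- diag(S) + pr$theta
    mu <- pr$nu + drop(pr$Lambda %*% pr$alpha)
    if (mean_structure) c(mu, S[lt]) else S[lt]
  }
  base <- mom_of(x)
  Delta <- matrix(0, length(base), length(x))
  h <- 1e-6 * pmax(abs(x), 1)
  for (j in seq_along(x)) {
    zp <- x; zp[j] <- zp[j] + h[j]
    zm <- x; zm[j] <- zm[j] - h[j]
    Delta[, j] <- (mom_of(zp) - mom_of(zm)) / (2 * h[j])
  }
  WD <- W %*% Delta
  U <- W - WD %*% solve(crossprod(Delta, WD)) %*% t(WD)
  sum(U * Gamma) / df
}

duplication_matrix <- function(p) {
  lt <- which(lower.tri(matrix(0, p, p), diag = TRUE))
  D <- matrix(0, p * p, length(lt))
  full <- matrix(seq_len(p * p), p, p)
  for (k in seq_along(lt)) {
    ij <- arrayInd(lt[k], c(p, p))
    D[full[ij[1], ij[2]], k] <- 1
    D[full[ij[2], ij[1]], k] <- 1
  }
  D
}
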