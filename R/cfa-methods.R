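# S3 methods for fitted CFA objects.

#' @export
print.vn_cfa <- function(x, ...) {
  if (identical(x$model, "saturated")) {
    cat("Saturated covariance model: T = 0, df = 0\n")
    return(invisible(x))
  }
  ng <- length(x$n)
  cat(sprintf("CFA fit (%s): %d factors, %d indicators, %s\n",
              x$model$kind, length(x$model$factors),
              length(x$model$indicators),
              if (ng > 1) sprintf("%d groups (%s invariance)", ng, x$level)
              else "1 group"))
  cat(sprintf("  chi^2(df) = %.1f (%d)", x$statistic, x$df))
  if (x$df > 0) cat(sprintf(", chi^2/df = %.2f, p = %.3g",
                            x$statistic / x$df, x$p.value))
  cat("\n")
  cat(sprintf("  CFI = %.3f, TLI = %.3f, RMSEA = %.3f, SRMR = %.3f\n",
              x$fit["CFI"], x$fit["TLI"], x$fit["RMSEA"], x$fit["SRMR"]))
  cat(sprintf("  AIC = %.1f, BIC = %.1f, logLik = %.1f (%d free parameters)\n",
              x$fit["AIC"], x$fit["BIC"], x$loglik, x$n_free))
  if (!is.na(x$scaling_factor))
    cat(sprintf("  robust scaling factor = %.3f, scaled chi^2 = %.1f\n",
                x$scaling_factor, x$statistic_scaled))
  invisible(x)
}

#' @export
summary.vn_cfa <- function(object, ...) {
  pt <- object$ptab[object$ptab$free, ]
  first <- !duplicated(pt$par_id)
  tab <- data.frame(label = pt$label[first],
                    matrix = pt$mat[first],
                    group = pt$group[first],
                    estimate = object$estimates[pt$par_id[first]],
                    se = object$se[pt$par_id[first]],
                    stringsAsFactors = FALSE)
  tab$z <- tab$estimate / tab$se
  tab$p <- 2 * stats::pnorm(-abs(tab$z))
  structure(list(fit = object, table = tab), class = "summary.vn_cfa")
}

#' @export
print.summary.vn_cfa <- function(x, digits = 3, ...) {
  print(x$fit)
  cat("\nParameter estimates:\n")
  tab <- x$table
  tab$estimate <- round(tab$estimate, digits)
  tab$se <- round(tab$se, digits)
  tab$z <- round(tab$z, 2)
  tab$p <- signif(tab$p, 2)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
coef.vn_cfa <- function(object, ...) object$estimates

#' @export
vcov.vn_cfa <- function(object, ...) object$vcov

#' @export
logLik.vn_cfa <- function(object, ...) {
  structure(object$loglik, df = object$n_free, nobs = sum(object$n),
            class = "logLik")
}

#' @export
fitted.vn_cfa <- function(object, ...) {
  lapply(object$params, function(p) list(Sigma = p$Sigma, mu = p$mu))
}

#' Residual moments of a CFA fit
#'
#' Per group, the raw residual `S - Sigma_hat` (and `xbar - mu_hat` under a
#' mean structure).
#' @param object a fitted [cfa()] model.
#' @param ... unused.
#' @export
residuals.vn_cfa <- function(object, ...) {
  lapply(seq_along(object$params), function(g) {
    list(cov = object$mom[[g]]$S - object$params[[g]]$Sigma,
         mean = if (object$mean_structure)
           object$mom[[g]]$xbar - object$params[[g]]$mu else NULL)
  })
}

#' Factor scores by the regression method
#'
#' `eta_hat = alpha + Phi Lambda' Sigma^-1 (x - mu_hat)`, using the fitted
#' group's parameters for each observation.
#'
#' @param fit a converged [cfa()] fit.
#' @param data indicator matrix (columns covering the model's indicators).
#' @param group optional group vector aligned with `data` rows (required for
#'   multi-group fits; levels must match the fitted groups).
#' @return matrix of factor scores (observations x factors).
#' @export
factor_scores <- function(fit, data, group = NULL) {
  stopifnot(inherits(fit, "vn_cfa"))
  if (identical(fit$model, "saturated"))
    vn_stop("factor scores need a latent-variable model", "varnet_input_error")
  data <- as.matrix(data)[, fit$model$indicators, drop = FALSE]
  ng <- length(fit$params)
  gf <- if (is.null(group)) {
    if (ng > 1) vn_stop("group is required for multi-group fits",
                        "varnet_input_error")
    factor(rep(names(fit$params)[1], nrow(data)),
           levels = names(fit$params))
  } else factor(group, levels = names(fit$params))
  M <- ncol(fit$params[[1]]$Lambda)
  out <- matrix(NA_real_, nrow(data), M,
                dimnames = list(rownames(data),
                                colnames(fit$params[[1]]$Lambda)))
  for (g in seq_len(ng)) {
    rows <- which(gf == names(fit$params)[g])
    if (!length(rows)) next
    pr <- fit$params[[g]]
    Sinv <- tryCatch(solve(pr$Sigma), error = function(e)
      vn_stop("implied covariance is singular", "varnet_input_error"))
    mu <- if (fit$mean_structure) pr$mu else fit$mom[[g]]$xbar
    xc <- sweep(data[rows, , drop = FALSE], 2, mu)
    A <- pr$Phi %*% t(pr$Lambda) %*% Sinv
    out[rows, ] <- sweep(xc %*% t(A), 2, pr$alpha, `+`)
  }
  out
}

#' @export
predict.vn_cfa <- function(object, newdata, group = NULL, ...) {
  factor_scores(object, newdata, group)
}

#' Standardized loading matrix of a fitted CFA
#'
#' Completely standardized solution: `Lambda* = Lambda diag(sqrt(diag(Phi)))
#' / sqrt(diag(Sigma))`.
#'
#' @param fit a fitted [cfa()] model.
#' @param group group index.
#' @return standardized loading matrix.
#' @export
standardized_loadings <- function(fit, group = 1) {
  pr <- fit$params[[group]]
  L <- sweep(pr$Lambda, 2, sqrt(diag(pr$Phi)), `*`)
  sweep(L, 1, sqrt(diag(pr$Sigma)), `/`)
}

#' Simulate indicator data from a fitted CFA
#'
#' Parametric-bootstrap draws from the fitted multivariate normal
#' (`N(mu_hat, Sigma_hat)` per group, using each group's fitted sample
#' size).
#'
#' @param object a fitted [cfa()] model.
#' @param nsim number of datasets.
#' @param seed RNG seed.
#' @param ... unused.
#' @return a list of `nsim` matrices (or the matrix itself when
#'   `nsim = 1`), each with a `"group"` attribute for multi-group fits.
#' @export
simulate.vn_cfa <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  one <- function() {
    out <- lapply(seq_along(object$params), function(g) {
      pr <- object$params[[g]]
      n <- object$n[g]
      mu <- if (object$mean_structure) pr$mu else object$mom[[g]]$xbar
      z <- matrix(stats::rnorm(n * length(mu)), n) %*% chol(pr$Sigma)
      sweep(z, 2, mu, `+`)
    })
    x <- do.call(rbind, out)
    colnames(x) <- names(object$params[[1]]$mu)
    attr(x, "group") <- rep(names(object$params), object$n)
    x
  }
  if (nsim == 1) one() else replicate(nsim, one(), simplify = FALSE)
}
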