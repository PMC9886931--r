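#' Incremental and absolute fit indices
#'
#' Standard normal-theory fit indices from a model test statistic and its
#' independence baseline:
#' `CFI = 1 - max(T - df, 0) / max(T_b - df_b, T - df, 0)`;
#' `TLI = ((T_b/df_b) - (T/df)) / ((T_b/df_b) - 1)` (clamped to `[0, 1]`,
#' flagged `NA` when the baseline ratio is 1);
#' `RMSEA = sqrt(G * max(T - df, 0) / (df * (n - G)))` for `G` groups (the
#' single-group case reduces to `sqrt(max(T - df, 0) / (df * (n - 1)))`);
#' `SRMR` is the root mean square of the standardized residuals of `S`
#' against the implied `Sigma`, diagonal included, when moments are supplied.
#'
#' @param statistic model test statistic T (chi-square scale).
#' @param df model degrees of freedom (> 0).
#' @param baseline_statistic,baseline_df independence-model statistic and df.
#' @param n total sample size.
#' @param S,Sigma observed and implied covariance matrices (single matrix or
#'   list per group) for SRMR; optional.
#' @param n_groups number of groups.
#' @return named numeric vector `c(CFI, TLI, RMSEA, SRMR)` (SRMR `NA` when
#'   moments are not given).
#' @export
fit_indices <- function(statistic, df, baseline_statistic, baseline_df, n,
                        S = NULL, Sigma = NULL, n_groups = 1) {
  stopifnot(df > 0, baseline_df > 0)
  d <- max(statistic - df, 0)
  d_b <- max(baseline_statistic - baseline_df, d, 0)
  CFI <- if (d_b == 0) 1 else 1 - d / d_b
  rb <- baseline_statistic / baseline_df
  TLI <- if (abs(rb - 1) < 1e-12) NA_real_ else
    (rb - statistic / df) / (rb - 1)
  if (!is.na(TLI)) TLI <- min(max(TLI, 0), 1)
  RMSEA <- sqrt(n_groups * max(statistic - df, 0) / (df * (n - n_groups)))
  SRMR <- NA_real_
  if (!is.null(S) && !is.null(Sigma)) {
    if (!is.list(S)) { S <- list(S); Sigma <- list(Sigma) }
    vals <- mapply(function(s, sg) {
      sd_ <- sqrt(diag(s))
      res <- (s - sg) / tcrossprod(sd_)
      lt <- lower.tri(res, diag = TRUE)
      c(sum(res[lt]^2), sum(lt))
    }, S, Sigma)
    SRMR <- sqrt(sum(vals[1, ]) / sum(vals[2, ]))
  }
  c(CFI = min(max(CFI, 0), 1), TLI = TLI, RMSEA = RMSEA, SRMR = SRMR)
}

#' Information criteria from a log-likelihood
#'
#' `AIC = -2 logLik + 2k`; `BIC = -2 logLik + k log(n)`.
#'
#' @param loglik model log-likelihood.
#' @param k number of free parameters.
#' @param n sample size.
#' @return named numeric vector `c(AIC, BIC)`.
#' @export
information_criteria <- function(loglik, k, n) {
  c(AIC = -2 * loglik + 2 * k, BIC = -2 * loglik + k * log(n))
}
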