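#' Fit a two-group measurement-invariance ladder
#'
#' Fits the four nested multi-group CFA models with progressively stringent
#' equality constraints -- configural (same pattern, all parameters
#' group-specific), metric (equal loadings, group-2 factor variances freed),
#' scalar (equal intercepts, group-2 factor means freed), strict (equal
#' residual variances) -- each warm-started from the previous solution, and
#' tabulates the chi-square differences and changes in fit indices between
#' adjacent levels.
#'
#' @param model a [cfa_model()].
#' @param data indicator matrix.
#' @param group two-group factor/character vector (first level = reference).
#' @param release named list of per-level constraint exemptions for partial
#'   invariance, e.g. `list(strict = c("Hb", "WBC"))` keeps those residuals
#'   group-specific at the strict level.
#' @param thresholds delta-fit-index cutoffs used by [evaluate_invariance()].
#' @return An object of class `vn_invariance`: list with `fits` (per level),
#'   `grid` (level x fit-measure table), `deltas` (adjacent-pair
#'   differences), `achieved`, `failed` (levels that did not converge),
#'   `groups`.
#' @export
invariance_ladder <- function(model, data, group, release = NULL,
                              thresholds = c(CFI = -0.01, TLI = -0.01,
                                             RMSEA = 0.015)) {
  gf <- factor(group)
  if (nlevels(gf) != 2)
    vn_stop("exactly 2 groups are required", "varnet_input_error")
  if (min(table(gf)) < 50)
    warning("a group has fewer than 50 observations; invariance fits may be unstable",
            call. = FALSE)
  levels_ <- c("configural", "metric", "scalar", "strict")
  fits <- list()
  failed <- character()
  prev <- NULL
  for (lv in levels_) {
    f <- tryCatch(
      cfa(model, data = data, group = gf, mean_structure = TRUE,
          level = lv, release = release, warm_start = prev,
          se = lv %in% c("scalar", "strict")),
      error = function(e) e)
    if (inherits(f, "error")) {
      failed <- c(failed, lv)
      break
    }
    fits[[lv]] <- f
    prev <- f
  }
  if (!length(fits))
    vn_stop("configural model did not converge", "varnet_convergence_error")

  grid <- do.call(rbind, lapply(names(fits), function(lv) {
    f <- fits[[lv]]
    data.frame(level = lv, chisq = f$statistic, df = f$df,
               chisq_df = f$statistic / f$df,
               CFI = unname(f$fit["CFI"]), TLI = unname(f$fit["TLI"]),
               RMSEA = unname(f$fit["RMSEA"]),
               AIC = unname(f$fit["AIC"]), BIC = unname(f$fit["BIC"]),
               stringsAsFactors = FALSE)
  }))

  deltas <- NULL
  if (nrow(grid) >= 2) {
    i <- 2:nrow(grid)
    dchi <- grid$chisq[i] - grid$chisq[i - 1]
    ddf <- grid$df[i] - grid$df[i - 1]
    deltas <- data.frame(
      comparison = paste(grid$level[i], grid$level[i - 1], sep = "-"),
      delta_chisq = dchi, delta_df = ddf,
      delta_p = stats::pchisq(pmax(dchi, 0), ddf, lower.tail = FALSE),
      delta_CFI = grid$CFI[i] - grid$CFI[i - 1],
      delta_TLI = grid$TLI[i] - grid$TLI[i - 1],
      delta_RMSEA = grid$RMSEA[i] - grid$RMSEA[i - 1],
      delta_AIC = grid$AIC[i] - grid$AIC[i - 1],
      delta_BIC = grid$BIC[i] - grid$BIC[i - 1],
      stringsAsFactors = FALSE)
  }
  achieved <- evaluate_invariance(deltas, thresholds,
                                  fitted_levels = grid$level)
  structure(list(fits = fits, grid = grid, deltas = deltas,
                 achieved = achieved, failed = failed,
                 thresholds = thresholds, groups = levels(gf),
                 model = model, release = release),
            class = "vn_invariance")
}

#' @rdname invariance_ladder
#' @export
fit_invariance_ladder <- invariance_ladder

#' Decide the achieved invariance level from delta fit indices
#'
#' Walks the ladder from configural upward and stops before the first step
#' whose fit degradation violates any threshold: `delta CFI < -0.01`,
#' `delta TLI < -0.01` or `delta RMSEA > 0.015` by default. The chi-square
#' difference p-value is reported in the deltas but plays no part in the
#' decision (it is overly sensitive to sample size).
#'
#' @param deltas the `deltas` table from [invariance_ladder()] (or `NULL`).
#' @param thresholds named cutoffs (`CFI`, `TLI` are lower bounds on the
#'   change; `RMSEA` an upper bound).
#' @param fitted_levels the levels actually fitted, in order.
#' @return the deepest acceptable level (character).
#' @export
evaluate_invariance <- function(deltas,
                                thresholds = c(CFI = -0.01, TLI = -0.01,
                                               RMSEA = 0.015),
                                fitted_levels = c("configural", "metric",
                                                  "scalar", "strict")) {
  achieved <- fitted_levels[1]
  if (is.null(deltas) || !nrow(deltas)) return(achieved)
  for (i in seq_len(nrow(deltas))) {
    ok <- deltas$delta_CFI[i] >= thresholds["CFI"] &&
      deltas$delta_TLI[i] >= thresholds["TLI"] &&
      deltas$delta_RMSEA[i] <= thresholds["RMSEA"]
    if (!ok) break
    achieved <- fitted_levels[i + 1]
  }
  achieved
}

#' Compare factor means between groups
#'
#' Reports the group-2 factor-mean contrasts of an invariance ladder at the
#' requested level (reference group fixed at 0), with Wald z tests. The
#' contrast is reported both in latent (unit reference variance) units and,
#' when `anchor_scale` is given (e.g. from a [cohort_spec()] anchor table),
#' on the indicator (LCV) scale.
#'
#' @param report a [invariance_ladder()] result.
#' @param level `"scalar"` or `"strict"` (must not exceed the achieved
#'   level).
#' @param anchor_scale optional named per-factor scale (LCV units per latent
#'   SD) used to add an `estimate_lcv` column.
#' @return data.frame with columns factor, estimate, se, z, p (and
#'   `estimate_lcv`).
#' @export
compare_factor_means <- function(report, level = "strict",
                                 anchor_scale = NULL) {
  stopifnot(inherits(report, "vn_invariance"))
  lv_order <- c("configural", "metric", "scalar", "strict")
  if (!level %in% c("scalar", "strict"))
    vn_stop("factor means are identified from the scalar level upward",
            "varnet_input_error")
  if (match(level, lv_order) > match(report$achieved, lv_order))
    vn_stop(sprintf("requested level '%s' exceeds achieved level '%s'",
                    level, report$achieved), "varnet_input_error")
  fit <- report$fits[[level]]
  labs <- names(fit$estimates)
  sel <- grep("^alpha:", labs)
  tab <- data.frame(factor = sub("^alpha:([^@]+)@.*$", "\\1", labs[sel]),
                    estimate = unname(fit$estimates[sel]),
                    se = unname(fit$se[sel]), stringsAsFactors = FALSE)
  tab$z <- tab$estimate / tab$se
  tab$p <- 2 * stats::pnorm(-abs(tab$z))
  if (!is.null(anchor_scale))
    tab$estimate_lcv <- tab$estimate * unname(anchor_scale[tab$factor])
  tab
}

#' @export
print.vn_invariance <- function(x, digits = 3, ...) {
  cat(sprintf("Measurement-invariance ladder (%s vs %s)\n",
              x$groups[1], x$groups[2]))
  g <- x$grid
  g$chisq <- round(g$chisq, 1); g$chisq_df <- round(g$chisq_df, 2)
  for (cn in c("CFI", "TLI", "RMSEA")) g[[cn]] <- round(g[[cn]], digits)
  for (cn in c("AIC", "BIC")) g[[cn]] <- round(g[[cn]], 0)
  print(g, row.names = FALSE)
  if (!is.null(x$deltas)) {
    cat("\nAdjacent-model differences:\n")
    d <- x$deltas
    d$delta_chisq <- round(d$delta_chisq, 1)
    d$delta_p <- signif(d$delta_p, 2)
    for (cn in c("delta_CFI", "delta_TLI", "delta_RMSEA"))
      d[[cn]] <- round(d[[cn]], 3)
    print(d[, c("comparison", "delta_chisq", "delta_df", "delta_p",
                "delta_CFI", "delta_TLI", "delta_RMSEA")], row.names = FALSE)
  }
  cat(sprintf("\nAchieved level: %s%s\n", x$achieved,
              if (length(x$failed)) sprintf(" (failed to fit: %s)",
                                            paste(x$failed, collapse = ", "))
              else ""))
  invisible(x)
}
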