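#' Choose the correlation method for a pair of variables
#'
#' Mirrors the mixed-method convention: any pair involving a binary variable
#' uses the point-biserial coefficient (a product-moment correlation on 0/1
#' coding); two normally distributed continuous variables use Pearson; any
#' other continuous pair uses Spearman. Normality tags typically come from
#' [ks_normality()] at alpha = 0.05.
#'
#' @param tag_a,tag_b per-variable tags, each a list/row with logical
#'   `binary` and `normal` entries.
#' @return `"point-biserial"`, `"pearson"` or `"spearman"`.
#' @export
choose_method <- function(tag_a, tag_b) {
  need <- function(tag, nm) {
    if (is.null(tag$binary) || (!isTRUE(tag$binary) && is.null(tag$normal)))
      vn_stop(sprintf("variable '%s' is missing binary/normal tags", nm),
              "varnet_input_error")
  }
  need(tag_a, "a"); need(tag_b, "b")
  if (isTRUE(tag_a$binary) || isTRUE(tag_b$binary)) return("point-biserial")
  if (isTRUE(tag_a$normal) && isTRUE(tag_b$normal)) return("pearson")
  "spearman"
}

#' Mixed-method correlation matrix
#'
#' Computes all pairwise correlations of the columns of `table`, choosing the
#' method per pair via [choose_method()]. Every method's two-sided p-value
#' uses the t approximation `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2`
#' degrees of freedom; p-values are deliberately not adjusted for multiple
#' comparisons.
#'
#' @param table data.frame or matrix of observations (binary variables coded
#'   0/1).
#' @param tags named list of per-variable tags (`binary`, `normal`). Missing
#'   tags are derived automatically: 0/1 columns are tagged binary, others by
#'   [ks_normality()] at alpha 0.05. `overrides` (named character vector,
#'   values `"spearman"` etc. applied when the named variable is in the pair)
#'   wins over the tag rule.
#' @param overrides optional named character vector of per-variable forced
#'   methods.
#' @return An object of class `vn_corr`: list with `variables`, square
#'   matrices `r`, `p`, `n`, character matrix `method`, and `tags`.
#' @export
correlation_matrix <- function(table, tags = NULL, overrides = NULL) {
  x <- as.data.frame(table)
  vars <- names(x)
  for (v in vars) {
    col <- x[[v]]
    if (!is.numeric(col))
      vn_stop(sprintf("column '%s' is not numeric", v), "varnet_input_error")
    if (stats::var(col, na.rm = TRUE) == 0)
      vn_stop(sprintf("column '%s' has zero variance", v), "varnet_input_error")
  }
  if (is.null(tags)) tags <- list()
  for (v in vars) {
    if (is.null(tags[[v]])) {
      col <- x[[v]][!is.na(x[[v]])]
      if (all(col %in% c(0, 1))) {
        tags[[v]] <- list(binary = TRUE, normal = FALSE)
      } else {
        tags[[v]] <- list(binary = FALSE,
                          normal = !ks_normality(col)$rejected)
      }
    }
  }
  p <- length(vars)
  r_m <- matrix(1, p, p, dimnames = list(vars, vars))
  p_m <- matrix(0, p, p, dimnames = list(vars, vars))
  n_m <- matrix(0L, p, p, dimnames = list(vars, vars))
  meth <- matrix(NA_character_, p, p, dimnames = list(vars, vars))
  for (i in seq_len(p)) n_m[i, i] <- sum(!is.na(x[[i]]))
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      ok <- stats::complete.cases(x[[i]], x[[j]])
      n <- sum(ok)
      if (n < 3)
        vn_stop(sprintf("fewer than 3 complete observations for %s-%s",
                        vars[i], vars[j]), "varnet_input_error")
      method <- choose_method(tags[[vars[i]]], tags[[vars[j]]])
      if (!is.null(overrides)) {
        hit <- intersect(names(overrides), vars[c(i, j)])
        if (length(hit)) method <- unname(overrides[hit[1]])
      }
      r <- if (method == "spearman") {
        stats::cor(x[[i]][ok], x[[j]][ok], method = "spearman")
      } else {
        stats::cor(x[[i]][ok], x[[j]][ok])  # pearson == point-biserial on 0/1
      }
      r_m[i, j] <- r_m[j, i] <- r
      p_m[i, j] <- p_m[j, i] <- cor_p_value(r, n)
      n_m[i, j] <- n_m[j, i] <- n
      meth[i, j] <- meth[j, i] <- method
    }
  }
  structure(list(variables = vars, r = r_m, p = p_m, n = n_m,
                 method = meth, tags = tags),
            class = "vn_corr")
}

#' @export
print.vn_corr <- function(x, ...) {
  k <- length(x$variables)
  cat(sprintf("Mixed-method correlation matrix: %d variables, %d pairs\n",
              k, k * (k - 1) / 2))
  tab <- table(x$method[upper.tri(x$method)])
  cat("  methods:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' Partition LCV pairs by hemodynamic membership
#'
#' Splits the unordered variable pairs into those made of blood biomarkers
#' only and those including at least one hemodynamic biomarker.
#'
#' @param variables character vector of LCV variable names.
#' @param hemodynamic subset of `variables` that are hemodynamic.
#' @return list with `blood_only` and `mixed` pair matrices (2 columns) and
#'   `counts = c(blood_only, mixed)`.
#' @export
pair_partition <- function(variables, hemodynamic) {
  if (!all(hemodynamic %in% variables))
    vn_stop("hemodynamic set must be a subset of the variables",
            "varnet_input_error")
  if (length(variables) < 2)
    return(list(blood_only = matrix(character(), 0, 2),
                mixed = matrix(character(), 0, 2),
                counts = c(blood_only = 0L, mixed = 0L)))
  pairs <- t(utils::combn(variables, 2))
  is_mixed <- pairs[, 1] %in% hemodynamic | pairs[, 2] %in% hemodynamic
  list(blood_only = pairs[!is_mixed, , drop = FALSE],
       mixed = pairs[is_mixed, , drop = FALSE],
       counts = c(blood_only = sum(!is_mixed), mixed = sum(is_mixed)))
}

#' Count significant and negative correlations in a subset
#'
#' Over the unordered pairs within `subset`, counts pairs with unadjusted
#' two-sided p below `alpha` and pairs with negative coefficients.
#'
#' @param corr a [correlation_matrix()] result.
#' @param subset variables to restrict to (default: all).
#' @param alpha significance level in (0, 1).
#' @return list with `n_pairs`, `n_significant`, `n_negative`,
#'   `pct_significant`.
#' @export
count_significant <- function(corr, subset = corr$variables, alpha = 0.05) {
  stopifnot(inherits(corr, "vn_corr"), alpha > 0, alpha < 1)
  if (!all(subset %in% corr$variables))
    vn_stop("subset must be contained in the correlation variables",
            "varnet_input_error")
  r <- corr$r[subset, subset, drop = FALSE]
  p <- corr$p[subset, subset, drop = FALSE]
  ut <- upper.tri(r)
  n_pairs <- sum(ut)
  n_sig <- sum(p[ut] < alpha)
  list(n_pairs = n_pairs, n_significant = n_sig,
       n_negative = sum(r[ut] < 0),
       pct_significant = if (n_pairs) 100 * n_sig / n_pairs else NA_real_)
}
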