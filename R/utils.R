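# Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

## Classed error so callers can distinguish degenerate inputs from bugs.
vn_stop <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "varnet_error"), call = call))
}

## Population (n-divisor) standard deviation -- the CV convention used
## throughout: CV = population SD / mean.
pop_sd <- function(x) {
  n <- length(x)
  sqrt(sum((x - mean(x))^2) / n)
}

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x >= 0 && x == round(x)
}

## Symmetry + PSD check for correlation/covariance matrices.
check_psd <- function(m, name = "matrix", tol = 1e-8) {
  if (!isSymmetric(unname(m), tol = 1e-8))
    vn_stop(sprintf("%s must be symmetric", name), "varnet_spec_error")
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -tol * max(abs(ev)))
    vn_stop(sprintf("%s is not positive semi-definite (min eigenvalue %.3g)",
                    name, min(ev)), "varnet_spec_error")
  invisible(TRUE)
}

## Two-sided p-value from the t-approximation used for all correlation
## methods: t = r * sqrt((n - 2) / (1 - r^2)) on n - 2 df.
cor_p_value <- function(r, n) {
  if (n < 3) return(NA_real_)
  r <- min(max(r, -1), 1)
  if (abs(r) >= 1) return(0)
  tval <- r * sqrt((n - 2) / (1 - r^2))
  2 * stats::pt(-abs(tval), df = n - 2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
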