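#' Mean, coefficient of variation and LCV of a measurement series
#'
#' The variability metric used throughout: `CV = population SD / mean` (SD
#' with divisor n, not n - 1) and `LCV = log10(CV)`. A series with zero
#' variance has an undefined LCV and raises a classed degenerate-series
#' error, because downstream correlation analyses cannot absorb `-Inf`.
#'
#' @param values numeric vector of at least 2 positive-mean measurements.
#' @return list with components `M`, `CV`, `LCV`.
#' @examples
#' lcv(c(90, 100, 110))  # M 100, CV 0.0816, LCV -1.088
#' @export
lcv <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2 || anyNA(values) || any(!is.finite(values)))
    vn_stop("at least 2 finite values are required", "varnet_input_error")
  M <- mean(values)
  if (M <= 0)
    vn_stop("series mean must be positive", "varnet_input_error")
  s <- pop_sd(values)
  if (s == 0)
    vn_stop("zero-variance series: LCV undefined", "varnet_degenerate_error")
  CV <- s / M
  list(M = M, CV = CV, LCV = log10(CV))
}

#' Per-patient variability summaries over calendar windows
#'
#' Aggregates long-format records into one (M, CV, LCV) summary per
#' patient x biomarker x window. Monthly windows follow calendar months of
#' the data year; the yearly window pools all measurements in the calendar
#' year. Windows with fewer than 2 measurements, or with zero variance, are
#' omitted with a warning.
#'
#' @param records data.frame with columns patient_id, date, biomarker, value.
#' @param window `"year"` or `"month"`.
#' @return data.frame with columns patient_id, biomarker, window, n, M, CV,
#'   LCV (for monthly windows, `window` is `"YYYY-MM"`; yearly, `"YYYY"`).
#' @export
variability_summary <- function(records, window = c("year", "month")) {
  window <- match.arg(window)
  needed <- c("patient_id", "date", "biomarker", "value")
  if (!all(needed %in% names(records)))
    vn_stop(sprintf("records must have columns: %s",
                    paste(needed, collapse = ", ")), "varnet_input_error")
  d <- as.Date(records$date)
  win <- if (window == "month") format(d, "%Y-%m") else format(d, "%Y")
  key <- paste(records$patient_id, records$biomarker, win, sep = "\r")
  kf <- factor(key)

  ## Grouped sums give mean and population SD in one pass.
  n_g <- tabulate(kf)
  s1 <- rowsum(records$value, kf, reorder = FALSE)[, 1]
  n_grp <- n_g[match(names(s1), levels(kf))]
  M <- s1 / n_grp
  ## second centered pass avoids cancellation for large-mean biomarkers
  dev2 <- (records$value - M[match(key, names(s1))])^2
  sd_pop <- sqrt(rowsum(dev2, kf, reorder = FALSE)[, 1] / n_grp)
  usable <- n_grp >= 2 & sd_pop > 0 & M > 0
  if (any(!usable))
    warning(sprintf("%d window(s) omitted (fewer than 2 usable measurements or zero variance)",
                    sum(!usable)), call. = FALSE)
  if (!any(usable)) {
    return(data.frame(patient_id = character(), biomarker = character(),
                      window = character(), n = integer(), M = numeric(),
                      CV = numeric(), LCV = numeric()))
  }
  parts <- do.call(rbind, strsplit(names(s1)[usable], "\r", fixed = TRUE))
  res <- data.frame(patient_id = parts[, 1], biomarker = parts[, 2],
                    window = parts[, 3], n = n_grp[usable],
                    M = M[usable], CV = sd_pop[usable] / M[usable],
                    LCV = log10(sd_pop[usable] / M[usable]),
                    stringsAsFactors = FALSE)
  res <- res[order(res$patient_id, res$biomarker, res$window), ]
  rownames(res) <- NULL
  res
}

#' Wide patient x biomarker LCV matrix
#'
#' Convenience reshape of the yearly [variability_summary()] into the
#' analysis matrix used by the correlation, EFA and CFA stages.
#'
#' @param records long-format records, or a `vn_cohort`.
#' @param value `"LCV"` or `"M"`.
#' @return numeric matrix, patients in rows, biomarkers in columns.
#' @export
lcv_matrix <- function(records, value = c("LCV", "M")) {
  value <- match.arg(value)
  if (inherits(records, "vn_cohort")) records <- records$records
  s <- variability_summary(records, "year")
  pts <- sort(unique(s$patient_id))
  bms <- unique(s$biomarker)
  m <- matrix(NA_real_, length(pts), length(bms),
              dimnames = list(pts, bms))
  m[cbind(match(s$patient_id, pts), match(s$biomarker, bms))] <- s[[value]]
  m
}

#' Cohort eligibility filter
#'
#' Keeps patients with more than 100 dialysis sessions, more than 21 attended
#' scheduled blood tests, and at least 6 months on dialysis at the start of
#' the observation window (both count thresholds strict).
#'
#' @param metadata data.frame with columns patient_id, sessions,
#'   tests_attended, vintage_years.
#' @param min_sessions,min_tests strict lower bounds on counts.
#' @param min_vintage_years minimum vintage (inclusive).
#' @return character vector of included patient_ids.
#' @export
eligibility_filter <- function(metadata, min_sessions = 100, min_tests = 21,
                               min_vintage_years = 0.5) {
  needed <- c("patient_id", "sessions", "tests_attended", "vintage_years")
  missing_f <- setdiff(needed, names(metadata))
  if (length(missing_f))
    vn_stop(sprintf("metadata is missing field(s): %s",
                    paste(missing_f, collapse = ", ")), "varnet_input_error")
  keep <- metadata$sessions > min_sessions &
    metadata$tests_attended > min_tests &
    metadata$vintage_years >= min_vintage_years
  metadata$patient_id[keep]
}

#' Paired seasonal comparison of monthly summaries
#'
#' Two-sided paired t-test of a monthly quantity (M or LCV) between two
#' months, over the patients observed in both (e.g. February vs August for a
#' winter blood-pressure peak).
#'
#' @param summaries monthly [variability_summary()] output for one biomarker.
#' @param month_a,month_b months 1-12, or `"YYYY-MM"` strings.
#' @param quantity `"M"` or `"LCV"`.
#' @return list with `t`, `df`, `p`, `n`, per-month `mean` and `sd`, and the
#'   mean paired difference `diff` (month_a minus month_b).
#' @export
paired_month_test <- function(summaries, month_a, month_b,
                              quantity = c("M", "LCV")) {
  quantity <- match.arg(quantity)
  mon <- sub("^[0-9]{4}-", "", summaries$window)
  key_of <- function(m) if (is.numeric(m)) sprintf("%02d", m) else sub("^[0-9]{4}-", "", m)
  a <- summaries[mon == key_of(month_a), c("patient_id", quantity)]
  b <- summaries[mon == key_of(month_b), c("patient_id", quantity)]
  shared <- intersect(a$patient_id, b$patient_id)
  if (length(shared) < 2)
    vn_stop("fewer than 2 patients observed in both months", "varnet_input_error")
  va <- a[[quantity]][match(shared, a$patient_id)]
  vb <- b[[quantity]][match(shared, b$patient_id)]
  dif <- va - vb
  if (stats::sd(dif) == 0) {
    if (all(dif == 0)) {
      ## identical months: no evidence of any difference
      return(list(t = 0, df = length(shared) - 1, p = 1, n = length(shared),
                  mean = c(a = mean(va), b = mean(vb)),
                  sd = c(a = stats::sd(va), b = stats::sd(vb)), diff = 0))
    }
    vn_stop("zero-variance paired differences", "varnet_degenerate_error")
  }
  tt <- stats::t.test(va, vb, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, n = length(shared),
       mean = c(a = mean(va), b = mean(vb)),
       sd = c(a = stats::sd(va), b = stats::sd(vb)),
       diff = mean(dif))
}

#' Kolmogorov-Smirnov check of marginal normality
#'
#' One-sample KS test against a normal with mean and SD estimated from the
#' sample. With estimated parameters the test is conservative (the Lilliefors
#' correction is deliberately not applied by default); a Monte-Carlo
#' calibrated variant is available via `monte_carlo`.
#'
#' @param values numeric vector, n >= 8.
#' @param alpha rejection level.
#' @param monte_carlo if `TRUE`, calibrate the p-value by simulation
#'   (`n_reps` draws) to account for the estimated parameters.
#' @param n_reps,seed Monte-Carlo settings.
#' @return list with `statistic`, `p`, `rejected`.
#' @export
ks_normality <- function(values, alpha = 0.05, monte_carlo = FALSE,
                         n_reps = 500, seed = 1) {
  values <- as.numeric(values)
  if (length(values) < 8)
    vn_stop("at least 8 values required", "varnet_input_error")
  if (stats::sd(values) == 0)
    vn_stop("constant input", "varnet_degenerate_error")
  stat_of <- function(x) {
    suppressWarnings(stats::ks.test(x, "pnorm", mean(x), stats::sd(x)))$statistic
  }
  D <- unname(stat_of(values))
  if (monte_carlo) {
    set.seed(seed)
    null_D <- replicate(n_reps, stat_of(stats::rnorm(length(values))))
    p <- (sum(null_D >= D) + 1) / (n_reps + 1)
  } else {
    p <- suppressWarnings(stats::ks.test(values, "pnorm", mean(values),
                                         stats::sd(values)))$p.value
  }
  list(statistic = D, p = p, rejected = p < alpha)
}
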