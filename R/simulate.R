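#' Simulate a longitudinal biomarker cohort
#'
#' Draws a cohort from a [cohort_spec()]: per patient, latent domain scores
#' `eta ~ MVN(alpha_g, Phi)`, true LCVs `nu + Lambda eta + eps`, a patient
#' mean level per biomarker, and scheduled measurements around that mean with
#' SD `10^LCV * M`. Hemodynamic biomarkers receive per-patient yearly
#' measurement counts from a right-skewed distribution (median 147) and a
#' seasonal cosine added through [add_seasonal_component()].
#'
#' @param spec a [cohort_spec()].
#' @param seed integer RNG seed; required, so cohorts are reproducible.
#' @return An object of class `vn_cohort`: list with `records` (long
#'   data.frame: patient_id, date, biomarker, value), `metadata` (group, age,
#'   sex, diabetes, vintage_years, bmi, sessions, tests_attended,
#'   sessions_per_week), and `truth` (`eta`: patient x factor; `lcv`:
#'   patient x biomarker true LCVs).
#' @examples
#' sp <- cohort_spec(n_patients = 20)
#' coh <- simulate_cohort(sp, seed = 1)
#' head(coh$records)
#' @export
simulate_cohort <- function(spec, seed) {
  validate_cohort_spec(spec)
  if (missing(seed) || is.null(seed))
    vn_stop("an explicit integer seed is required", "varnet_seed_error")
  set.seed(seed)

  n <- spec$n_patients
  ids <- spec$biomarkers
  m <- length(spec$factors)
  pid <- sprintf("P%04d", seq_len(n))

  ## Deterministic group block sizes (largest-remainder rounding).
  sizes <- floor(spec$groups$fraction * n)
  rem <- order(spec$groups$fraction * n - sizes, decreasing = TRUE)
  for (k in seq_len(n - sum(sizes))) sizes[rem[k]] <- sizes[rem[k]] + 1L
  grp <- rep(spec$groups$label, sizes)

  ## Latent domain scores.
  R <- chol(spec$factor_corr)
  eta <- matrix(stats::rnorm(n * m), n, m) %*% R
  eta <- eta + spec$groups$offset_eta[match(grp, spec$groups$label), , drop = FALSE]
  dimnames(eta) <- list(pid, spec$factors)

  ## True LCVs.
  lcv <- matrix(rep(spec$lcv_intercepts, each = n), n, length(ids)) +
    eta %*% t(spec$loadings) +
    matrix(stats::rnorm(n * length(ids)), n) %*%
      diag(spec$lcv_residual_sd, length(ids))
  dimnames(lcv) <- list(pid, ids)

  ## Patient mean levels, truncated positive.
  M <- matrix(stats::rnorm(n * length(ids), rep(spec$level_mean, each = n),
                           rep(spec$level_sd, each = n)), n, length(ids),
              dimnames = list(pid, ids))
  bad <- which(M <= 0)
  while (length(bad)) {
    j <- (bad - 1) %/% n + 1
    M[bad] <- stats::rnorm(length(bad), spec$level_mean[j], spec$level_sd[j])
    bad <- bad[M[bad] <= 0]
  }

  year <- spec$year
  all_days <- seq(as.Date(sprintf("%d-01-01", year)),
                  as.Date(sprintf("%d-12-31", year)), by = "day")
  rec <- vector("list", length(ids))
  for (j in seq_along(ids)) {
    b <- ids[j]
    k <- spec$schedule[b]
    if (k >= 52) {
      counts <- hemodynamic_counts(n)
      dates <- lapply(counts, function(ct) sort(sample(all_days, ct)))
    } else {
      dates <- rep(list(scheduled_dates(k, year)), n)
      counts <- rep(length(dates[[1]]), n)
    }
    tot <- sum(counts)
    p_idx <- rep(seq_len(n), counts)
    mu <- M[p_idx, j]
    sdv <- 10^lcv[p_idx, j] * mu
    val <- draw_measurements(mu, sdv, spec$measurement_dist)
    rec[[j]] <- data.frame(patient_id = pid[p_idx],
                           date = as.Date(unlist(dates), origin = "1970-01-01"),
                           biomarker = b, value = val,
                           stringsAsFactors = FALSE)
  }
  records <- do.call(rbind, rec)
  ord <- order(records$patient_id, records$biomarker, records$date)
  records <- records[ord, ]
  rownames(records) <- NULL

  ## Seasonal cycles (hemodynamic by default) added through the public op.
  for (b in ids) {
    amp <- spec$seasonal[b, "amplitude"]
    if (amp > 0)
      records <- add_seasonal_component(records, b, amp,
                                        spec$seasonal[b, "peak_month"])
  }

  metadata <- simulate_metadata(pid, grp)
  structure(list(records = records, metadata = metadata,
                 truth = list(eta = eta, lcv = lcv),
                 spec = spec, seed = seed),
            class = "vn_cohort")
}

#' @rdname simulate_cohort
#' @export
generate_cohort <- simulate_cohort

## Per-patient yearly pre-dialysis measurement counts: 160 - lognormal,
## giving median ~147 and IQR ~118-156, clamped to [12, 159].
hemodynamic_counts <- function(n) {
  y <- exp(stats::rnorm(n, 2.565, 1.744))
  pmin(pmax(round(160 - y), 12L), 159L)
}

## Exact probability mass of the count distribution above (used for
## calibration expectations).
hemodynamic_count_dist <- function() {
  k <- 12:159
  upper <- ifelse(k == 12, Inf, 160 - k + 0.5)   # y large -> clamped to 12
  lower <- ifelse(k == 159, -Inf, 160 - k - 0.5)
  p <- stats::plnorm(upper, 2.565, 1.744) - stats::plnorm(lower, 2.565, 1.744)
  list(k = k, p = p / sum(p))
}

## Fixed blood-draw calendars: twice-monthly (5th/19th), monthly (5th),
## bi-monthly (odd months, 5th).
scheduled_dates <- function(k, year) {
  if (k == 24) {
    d <- as.Date(sprintf("%d-%02d-%02d", year, rep(1:12, each = 2), c(5, 19)))
  } else if (k == 12) {
    d <- as.Date(sprintf("%d-%02d-05", year, 1:12))
  } else if (k == 6) {
    d <- as.Date(sprintf("%d-%02d-05", year, seq(1, 11, 2)))
  } else {
    d <- as.Date(sprintf("%d-01-01", year)) +
      round(seq(0, 364, length.out = k))
  }
  d
}

draw_measurements <- function(mu, sdv, dist) {
  if (dist == "lognormal") {
    cv <- sdv / mu
    sdlog <- sqrt(log1p(cv^2))
    return(stats::rlnorm(length(mu), log(mu) - sdlog^2 / 2, sdlog))
  }
  val <- stats::rnorm(length(mu), mu, sdv)
  bad <- which(val <= 0)
  while (length(bad)) {                      # CVs ~<= 0.2: rare, cheap
    val[bad] <- stats::rnorm(length(bad), mu[bad], sdv[bad])
    bad <- bad[val[bad] <= 0]
  }
  val
}

simulate_metadata <- function(pid, grp) {
  n <- length(pid)
  age <- truncated_normal(n, 62.9, 11.9, 25, 95)
  vintage <- pmax(stats::rlnorm(n, 2.141, 0.730), 0.5)
  bmi <- truncated_normal(n, 23.5, 5.0, 13, 45)
  spw <- ifelse(stats::runif(n) < 327 / 334, 3L, 2L)
  sessions <- round(52.18 * spw) - stats::rpois(n, 2)
  tests <- 24L - stats::rbinom(n, 2L, 0.05)
  data.frame(patient_id = pid, group = grp,
             age = round(age, 1),
             sex = ifelse(stats::runif(n) < 255 / 334, "M", "F"),
             diabetes = as.integer(grp == "diabetic"),
             vintage_years = round(vintage, 2),
             bmi = round(bmi, 1),
             sessions = sessions, tests_attended = tests,
             sessions_per_week = spw,
             stringsAsFactors = FALSE)
}

truncated_normal <- function(n, mean, sd, lo, hi) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lo | x > hi)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < lo | x[bad] > hi]
  }
  x
}

#' Add a seasonal cosine to one biomarker's measurements
#'
#' Adds `amplitude * cos(2 * pi * (month - peak_month) / 12)` to every
#' measurement of `biomarker`, so the annual cycle peaks at `peak_month`
#' (default 2, a winter blood-pressure peak).
#'
#' @param records long-format records (patient_id, date, biomarker, value).
#' @param biomarker biomarker id present in `records`.
#' @param amplitude non-negative amplitude, in biomarker units.
#' @param peak_month month (1-12) at which the cycle peaks.
#' @return `records` with the cycle added to that biomarker's values.
#' @export
add_seasonal_component <- function(records, biomarker, amplitude,
                                   peak_month = 2) {
  if (amplitude < 0)
    vn_stop("amplitude must be non-negative", "varnet_spec_error")
  sel <- records$biomarker == biomarker
  if (!any(sel))
    vn_stop(sprintf("unknown biomarker '%s'", biomarker), "varnet_spec_error")
  if (amplitude == 0) return(records)
  month <- as.integer(format(as.Date(records$date[sel]), "%m"))
  records$value[sel] <- records$value[sel] +
    amplitude * cos(2 * pi * (month - peak_month) / 12)
  records
}

#' @export
print.vn_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d patients, %d biomarkers, %d records (seed %d)\n",
              nrow(x$metadata), length(unique(x$records$biomarker)),
              nrow(x$records), x$seed))
  tab <- table(x$metadata$group)
  cat("  groups:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' Write a cohort to CSV files
#'
#' Writes `records.csv`, `metadata.csv`, `truth_eta.csv` and `truth_lcv.csv`
#' into `dir` (created if needed), all UTF-8 with header rows and ISO-8601
#' dates.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(cohort$records, file.path(dir, "records.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$metadata, file.path(dir, "metadata.csv"),
                   row.names = FALSE)
  eta <- data.frame(patient_id = rownames(cohort$truth$eta),
                    cohort$truth$eta, check.names = FALSE)
  utils::write.csv(eta, file.path(dir, "truth_eta.csv"), row.names = FALSE)
  lcv <- data.frame(patient_id = rownames(cohort$truth$lcv),
                    cohort$truth$lcv, check.names = FALSE)
  utils::write.csv(lcv, file.path(dir, "truth_lcv.csv"), row.names = FALSE)
  invisible(dir)
}
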