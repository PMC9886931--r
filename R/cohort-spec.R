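#' Reference hemodialysis biomarker panel
#'
#' Returns the built-in 22-biomarker panel (19 blood, 3 hemodynamic) used by
#' the default cohort specification: marginal means and SDs of the per-patient
#' annual mean (`level_mean`, `level_sd`, in biomarker units), marginal mean
#' and SD of the realized one-year LCV (log10 coefficient of variation),
#' measurement schedule (tests per year), and the default seasonal cycle
#' (amplitude in biomarker units, peaking in winter) for the hemodynamic
#' markers measured at every dialysis session.
#'
#' @return A data.frame with one row per biomarker.
#' @export
hd_biomarker_panel <- function() {
  p <- utils::read.table(header = TRUE, text = "
id    type        schedule level_mean level_sd lcv_mean lcv_sd seasonal_amp seasonal_peak
SBP   hemodynamic 147      150.8      18.3     -0.99    0.10   3.9          2
DBP   hemodynamic 147       80.0      10.8     -0.99    0.11   2.4          2
PR    hemodynamic 147       75.9      10.0     -1.11    0.12   0.2          2
WBC   blood       24       6325       1572     -0.93    0.15   0            2
Hb    blood       24         11.1     0.7      -1.24    0.18   0            2
Plat  blood       24         20.0     6.0      -1.03    0.18   0            2
TP    blood       12          6.3     0.4      -1.50    0.15   0            2
Alb   blood       24          3.6     0.3      -1.36    0.15   0            2
AST   blood       6          13.8     6.7      -0.69    0.26   0            2
ALT   blood       6          11.6     6.4      -0.75    0.28   0            2
LDH   blood       6         179       46       -1.11    0.18   0            2
ALP   blood       6         224       82       -0.97    0.23   0            2
BUN   blood       24         64.5     12.3     -0.91    0.14   0            2
Cr    blood       24         11.7     2.7      -1.26    0.18   0            2
UA    blood       12          7.2     1.2      -1.08    0.17   0            2
Na    blood       12        137.9     2.3      -1.96    0.13   0            2
K     blood       24          5.0     0.5      -1.10    0.15   0            2
Cl    blood       12        103.3     2.7      -1.79    0.14   0            2
Ca    blood       24          8.6     0.5      -1.42    0.18   0            2
P     blood       24          5.3     0.9      -0.80    0.14   0            2
LDL   blood       6          86.7     26.5     -1.02    0.22   0            2
HDL   blood       6          45.0     13.2     -1.09    0.21   0            2
", stringsAsFactors = FALSE)
  rownames(p) <- p$id
  p
}

#' Standardized loadings of the six regulatory domains
#'
#' The default loading matrix linking each biomarker's LCV to the six latent
#' regulatory domains (metabolism, circulation, liver, salt, inflammation,
#' protein). Values are standardized (correlation-metric) loadings; entries
#' below 0.1 in magnitude are zero.
#'
#' @return A 22 x 6 numeric matrix (rows: biomarkers, columns: factors).
#' @export
hd_panel_loadings <- function() {
  f <- c("metabolism", "circulation", "liver", "salt", "inflammation", "protein")
  ids <- hd_biomarker_panel()$id
  L <- matrix(0, length(ids), length(f), dimnames = list(ids, f))
  set_l <- function(id, ...) {
    v <- c(...)
    L[id, names(v)] <<- v
  }
  set_l("BUN",  metabolism = 0.82)
  set_l("Cr",   metabolism = 0.61)
  set_l("K",    metabolism = 0.69)
  set_l("P",    metabolism = 0.61, circulation = -0.11, inflammation = 0.11)
  set_l("UA",   metabolism = 0.44, circulation = -0.20, liver = 0.14)
  set_l("SBP",  circulation = 0.78)
  set_l("DBP",  circulation = 1.00)
  set_l("AST",  liver = 0.94)
  set_l("ALT",  liver = 0.72, metabolism = 0.11, inflammation = -0.12)
  set_l("Na",   salt = 0.76, protein = 0.11)
  set_l("Cl",   salt = 0.88)
  set_l("WBC",  inflammation = 0.54)
  set_l("Plat", inflammation = 0.84)
  set_l("TP",   protein = 0.88)
  set_l("Alb",  protein = 0.61, metabolism = 0.31)
  set_l("Hb",   inflammation = 0.34, metabolism = 0.21)
  set_l("LDH",  inflammation = 0.27, metabolism = 0.21, liver = 0.10)
  set_l("ALP",  liver = 0.33)
  set_l("Ca",   metabolism = 0.22, salt = 0.13, protein = 0.17)
  set_l("LDL",  metabolism = 0.29, inflammation = 0.16)
  set_l("HDL",  metabolism = 0.14, liver = 0.17, inflammation = 0.16)
  set_l("PR",   circulation = 0.25, protein = 0.17, metabolism = 0.12,
        inflammation = 0.11)
  L
}

default_factor_corr <- function() {
  f <- colnames(hd_panel_loadings())
  m <- matrix(0.35, 6, 6, dimnames = list(f, f))
  m["metabolism", ] <- m[, "metabolism"] <- 0.5
  diag(m) <- 1
  m
}

default_groups <- function() {
  offs <- rbind(
    `non-diabetic` = c(0, 0, 0, 0, 0, 0),
    diabetic       = c(0.049, 0.009, 0.021, 0.034, 0.005, -0.006)
  )
  colnames(offs) <- colnames(hd_panel_loadings())
  list(label = c("non-diabetic", "diabetic"),
       fraction = c(191, 143) / 334,
       offset_lcv = offs)
}

#' Specify a synthetic biomarker cohort
#'
#' Builds a generative specification for longitudinal biomarker panels whose
#' per-patient variabilities (LCV = log10 of the population-SD/mean
#' coefficient of variation) follow a latent factor model: for patient i in
#' group g, `eta_i ~ MVN(alpha_g, Phi)` and
#' `LCV_ij = nu_j + Lambda_j eta_i + eps_ij`, with measurements drawn around a
#' patient-specific mean at the scheduled frequency. The defaults reproduce
#' the built-in hemodialysis panel ([hd_biomarker_panel()]), the six-domain
#' loading structure ([hd_panel_loadings()]), and a diabetic/non-diabetic
#' split with domain-mean offsets on the LCV scale.
#'
#' Marginal calibration: standardized loadings are scaled by the target LCV
#' SDs; when `absorb_sampling_noise` is `TRUE` (default) the residual factor-
#' model variance is reduced by the delta-method sampling variance of a
#' k-measurement LCV estimate, so that *realized* LCVs computed from the
#' generated records match the declared marginal SDs. Rows whose implied
#' communality would leave less than 2% residual variance (e.g. a printed
#' loading of 1.00) are rescaled and flagged.
#'
#' @param n_patients number of patients.
#' @param groups list with `label`, `fraction` (summing to 1) and
#'   `offset_lcv`, a group x factor matrix of factor-mean offsets expressed on
#'   the LCV (log10) scale of each factor's anchor indicator.
#' @param loadings standardized biomarker x factor loading matrix.
#' @param factor_corr factor correlation matrix `Phi` (unit diagonal, PSD).
#' @param level_mean,level_sd per-biomarker mean and SD of the patient-level
#'   annual mean, in biomarker units (must be positive means).
#' @param lcv_mean,lcv_sd per-biomarker target marginal mean and SD of the
#'   realized LCV.
#' @param schedule per-biomarker measurements per year; hemodynamic markers
#'   (schedule >= 52) draw per-patient counts from a discretized right-skewed
#'   distribution with median 147.
#' @param seasonal data.frame-like with per-biomarker `amplitude` (biomarker
#'   units) and `peak_month`.
#' @param hemodynamic character vector of hemodynamic biomarker ids.
#' @param year calendar year the records cover.
#' @param measurement_dist `"normal"` (Gaussian around the patient mean,
#'   resampled if non-positive) or `"lognormal"`.
#' @param absorb_sampling_noise see Details.
#' @return An object of class `vn_cohort_spec`.
#' @seealso [simulate_cohort()], [implied_lcv_cov()]
#' @export
cohort_spec <- function(n_patients = 334,
                        groups = default_groups(),
                        loadings = hd_panel_loadings(),
                        factor_corr = default_factor_corr(),
                        level_mean = NULL, level_sd = NULL,
                        lcv_mean = NULL, lcv_sd = NULL,
                        schedule = NULL,
                        seasonal = NULL,
                        hemodynamic = c("SBP", "DBP", "PR"),
                        year = 2020,
                        measurement_dist = c("normal", "lognormal"),
                        absorb_sampling_noise = TRUE) {
  panel <- hd_biomarker_panel()
  ids <- rownames(loadings)
  default_for <- function(x, col) {
    if (!is.null(x)) return(x[ids])
    if (!all(ids %in% rownames(panel)))
      vn_stop("non-panel biomarkers need explicit marginal parameters",
              "varnet_spec_error")
    stats::setNames(panel[ids, col], ids)
  }
  level_mean <- default_for(level_mean, "level_mean")
  level_sd <- default_for(level_sd, "level_sd")
  lcv_mean <- default_for(lcv_mean, "lcv_mean")
  lcv_sd <- default_for(lcv_sd, "lcv_sd")
  schedule <- default_for(schedule, "schedule")
  if (is.null(seasonal)) {
    seasonal <- data.frame(amplitude = panel[ids, "seasonal_amp"],
                           peak_month = panel[ids, "seasonal_peak"],
                           row.names = ids)
  }
  measurement_dist <- match.arg(measurement_dist)

  if (abs(sum(groups$fraction) - 1) > 1e-8)
    vn_stop("group fractions must sum to 1", "varnet_spec_error")
  check_psd(factor_corr, "factor_corr")
  if (any(abs(diag(factor_corr) - 1) > 1e-8))
    vn_stop("factor_corr must have a unit diagonal", "varnet_spec_error")
  if (any(level_mean <= 0))
    vn_stop("all level_mean must be positive", "varnet_spec_error")

  ## Raw-scale loadings: standardized loadings refer to the realized-LCV
  ## correlation metric, so scale rows by the target marginal SD.
  lam_raw <- loadings * lcv_sd
  cv <- 10^lcv_mean
  ## Exact normal-theory moments of log10(sample CV) from k measurements
  ## (n-divisor SD): downward mean bias and extra between-patient variance.
  if (absorb_sampling_noise) {
    ## For session-linked markers the per-patient count k is itself random;
    ## use expectations over the count distribution.
    tri_term <- dig_term <- schedule * 0
    for (j in seq_along(schedule)) {
      k <- if (schedule[j] >= 52) hemodynamic_count_dist() else
        list(k = schedule[j], p = 1)
      tri_term[j] <- sum(k$p * (trigamma((k$k - 1) / 2) / 4 + cv[j]^2 / k$k))
      dig_term[j] <- sum(k$p * 0.5 * (digamma((k$k - 1) / 2) + log(2) -
                                        log(k$k)))
    }
    noise_var <- tri_term / log(10)^2
    lcv_bias <- dig_term / log(10)
  } else {
    noise_var <- lcv_bias <- stats::setNames(rep(0, length(ids)), ids)
  }
  h2 <- rowSums((lam_raw %*% factor_corr) * lam_raw)
  floor_var <- 0.02 * lcv_sd^2
  resid <- lcv_sd^2 - h2 - noise_var
  heywood <- resid < floor_var
  if (any(heywood)) {
    scale <- sqrt(pmax(lcv_sd^2 - noise_var - floor_var, floor_var) / h2)
    lam_raw[heywood, ] <- lam_raw[heywood, , drop = FALSE] * scale[heywood]
    resid[heywood] <- floor_var[heywood]
  }
  theta <- resid

  ## Anchor scale per factor: the strongest raw loading, used to translate
  ## LCV-scale group offsets into latent (unit-variance) units.
  anchor_idx <- apply(abs(lam_raw), 2, which.max)
  anchor <- data.frame(indicator = ids[anchor_idx],
                       scale = abs(lam_raw[cbind(anchor_idx, seq_len(ncol(lam_raw)))]),
                       row.names = colnames(loadings))
  offset_eta <- sweep(groups$offset_lcv, 2,
                      ifelse(anchor$scale > 0, anchor$scale, 1), `/`)
  offset_eta[, anchor$scale == 0] <- 0  # unused factors carry no offset

  ## Intercepts chosen so the *mixture* marginal mean of realized LCVs hits
  ## the target: subtract the group-mixture shift and the sampling bias.
  mix_eta <- colSums(groups$fraction * offset_eta)
  nu <- lcv_mean - lcv_bias - drop(lam_raw %*% mix_eta)

  spec <- structure(list(
    n_patients = n_patients,
    groups = list(label = groups$label, fraction = groups$fraction,
                  offset_lcv = groups$offset_lcv, offset_eta = offset_eta),
    loadings_std = loadings, loadings = lam_raw,
    factor_corr = factor_corr, factors = colnames(loadings),
    biomarkers = ids, hemodynamic = intersect(hemodynamic, ids),
    lcv_intercepts = nu, lcv_residual_sd = sqrt(theta),
    sampling_noise_var = noise_var,
    level_mean = level_mean, level_sd = level_sd,
    lcv_mean = lcv_mean, lcv_sd = lcv_sd,
    schedule = schedule, seasonal = seasonal, year = year,
    measurement_dist = measurement_dist,
    absorb_sampling_noise = absorb_sampling_noise,
    heywood = ids[heywood], anchor = anchor
  ), class = "vn_cohort_spec")
  validate_cohort_spec(spec)
  spec
}

#' @rdname cohort_spec
#' @export
default_cohort_spec <- function() cohort_spec()

validate_cohort_spec <- function(spec) {
  stopifnot(inherits(spec, "vn_cohort_spec"))
  check_psd(spec$factor_corr, "factor_corr")
  if (any(spec$lcv_residual_sd <= 0))
    vn_stop("all residual LCV SDs must be positive", "varnet_spec_error")
  if (any(spec$level_mean <= 0))
    vn_stop("all level means must be positive", "varnet_spec_error")
  if (abs(sum(spec$groups$fraction) - 1) > 1e-8)
    vn_stop("group fractions must sum to 1", "varnet_spec_error")
  implied <- sqrt(diag(implied_lcv_cov(spec)))
  if (any(abs(implied - spec$lcv_sd) > 1e-6))
    vn_stop("implied marginal LCV SDs do not match declared targets",
            "varnet_spec_error")
  invisible(spec)
}

#' Model-implied LCV covariance of a cohort specification
#'
#' Returns `Lambda Phi Lambda' + Theta`, optionally plus the delta-method
#' sampling-noise variance of the realized k-measurement LCV estimates (the
#' scale on which empirical one-year LCV panels live).
#'
#' @param spec a [cohort_spec()] object.
#' @param include_sampling_noise add the per-biomarker CV-estimation variance.
#' @param standardized return a correlation matrix.
#' @return A biomarker x biomarker covariance (or correlation) matrix.
#' @export
implied_lcv_cov <- function(spec, include_sampling_noise = TRUE,
                            standardized = FALSE) {
  S <- spec$loadings %*% spec$factor_corr %*% t(spec$loadings)
  diag(S) <- diag(S) + spec$lcv_residual_sd^2 +
    if (include_sampling_noise) spec$sampling_noise_var else 0
  if (standardized) S <- stats::cov2cor(S)
  S
}

#' @export
print.vn_cohort_spec <- function(x, ...) {
  cat("Synthetic cohort specification\n")
  cat(sprintf("  %d patients, %d biomarkers (%d hemodynamic), %d latent domains\n",
              x$n_patients, length(x$biomarkers), length(x$hemodynamic),
              length(x$factors)))
  cat(sprintf("  groups: %s\n",
              paste(sprintf("%s (%.0f%%)", x$groups$label,
                            100 * x$groups$fraction), collapse = ", ")))
  cat(sprintf("  schedules/yr: %s\n",
              paste(sort(unique(x$schedule)), collapse = ", ")))
  if (length(x$heywood))
    cat(sprintf("  communality capped for: %s\n",
                paste(x$heywood, collapse = ", ")))
  invisible(x)
}

#' Read a cohort specification from a declarative config file
#'
#' YAML file whose keys mirror the [cohort_spec()] arguments: scalar
#' settings (`n_patients`, `year`, `measurement_dist`,
#' `absorb_sampling_noise`), named per-biomarker maps (`level_mean`,
#' `level_sd`, `lcv_mean`, `lcv_sd`, `schedule`), `groups` (a list of
#' entries with `label`, `fraction` and `offset_lcv`, the per-factor
#' offsets on the LCV scale), and `seasonal` (per-biomarker `amplitude`
#' and `peak_month`). Keys not present keep the panel defaults; biomarker
#' maps may override a subset of the 22 built-in markers.
#'
#' @param path YAML file path.
#' @return A `vn_cohort_spec`.
#' @export
read_cohort_spec <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    vn_stop("the 'yaml' package is required to read config files",
            "varnet_input_error")
  cfg <- yaml::read_yaml(path)
  args <- list()
  for (k in c("n_patients", "year", "measurement_dist",
              "absorb_sampling_noise"))
    if (!is.null(cfg[[k]])) args[[k]] <- cfg[[k]]
  panel <- hd_biomarker_panel()
  for (k in c("level_mean", "level_sd", "lcv_mean", "lcv_sd", "schedule")) {
    if (!is.null(cfg[[k]])) {
      full <- stats::setNames(panel[[k]], panel$id)
      ov <- unlist(cfg[[k]])
      full[names(ov)] <- ov
      args[[k]] <- full
    }
  }
  if (!is.null(cfg$groups)) {
    labs <- vapply(cfg$groups, `[[`, "", "label")
    fr <- vapply(cfg$groups, function(g) as.numeric(g$fraction), 0)
    offs <- do.call(rbind, lapply(cfg$groups, function(g)
      as.numeric(g$offset_lcv %||% rep(0, 6))))
    rownames(offs) <- labs
    colnames(offs) <- colnames(hd_panel_loadings())
    args$groups <- list(label = labs, fraction = fr, offset_lcv = offs)
  }
  if (!is.null(cfg$seasonal)) {
    seas <- data.frame(amplitude = panel$seasonal_amp,
                       peak_month = panel$seasonal_peak,
                       row.names = panel$id)
    for (b in names(cfg$seasonal)) {
      seas[b, "amplitude"] <- cfg$seasonal[[b]]$amplitude %||% seas[b, "amplitude"]
      seas[b, "peak_month"] <- cfg$seasonal[[b]]$peak_month %||% seas[b, "peak_month"]
    }
    args$seasonal <- seas
  }
  do.call(cohort_spec, args)
}
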