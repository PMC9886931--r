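# End-to-end orchestration: simulate/load -> variability -> correlations ->
# network -> EFA -> CFA -> invariance -> report bundle.

## Small stable FNV-1a hash so manifests can prove two runs used one config.
config_hash <- function(obj) {
  bytes <- utf8ToInt(paste(deparse(obj), collapse = "\n"))
  h <- 2166136261
  for (b in bytes) h <- bitwAnd(bitwXor(h, b) * 16777619, 4294967295)
  sprintf("%08x", h)
}

#' Default pipeline configuration
#'
#' @param output_dir where the report bundle is written.
#' @param records,metadata CSV paths (long records and per-patient
#'   metadata); leave `NULL` to simulate from `spec`.
#' @param spec a [cohort_spec()] used when simulating.
#' @param seed master seed (cohort simulation, EFA restarts, layout).
#' @param alpha significance level.
#' @param n_factors EFA factor count.
#' @param model a [cfa_model()] or path readable by [read_cfa_model()].
#' @param group_var metadata column defining the two-group contrast
#'   (`NULL` skips the invariance stage).
#' @param overrides named per-variable correlation-method overrides.
#' @param thresholds delta-fit-index thresholds.
#' @param layout_seed seed recorded for the network layout.
#' @param robust compute the robust scaled statistic in the single-group CFA.
#' @return a named list (class `vn_config`).
#' @export
pipeline_config <- function(output_dir, records = NULL, metadata = NULL,
                            spec = NULL, seed = 1, alpha = 0.05,
                            n_factors = 6, model = NULL, group_var = "group",
                            overrides = NULL,
                            thresholds = c(CFI = -0.01, TLI = -0.01,
                                           RMSEA = 0.015),
                            layout_seed = 42, robust = FALSE) {
  structure(list(output_dir = output_dir, records = records,
                 metadata = metadata, spec = spec, seed = seed,
                 alpha = alpha, n_factors = n_factors, model = model,
                 group_var = group_var, overrides = overrides,
                 thresholds = thresholds, layout_seed = layout_seed,
                 robust = robust),
            class = "vn_config")
}

#' Run the full variability-network pipeline
#'
#' Executes every analysis stage in order and writes the documented artifact
#' bundle (`lcv_table.csv`, `corr_matrix.csv`, `corr_long.csv`,
#' `network.graphml`, `edges.csv`, `layout.csv`, `centralities.csv`,
#' `efa_report.json`, `efa_loadings.csv`, `cfa_fit.json`, `table3.csv`,
#' `invariance_report.json` when a grouping is configured, and
#' `manifest.json` recording seeds and the config hash). Reruns with the
#' same configuration are byte-identical.
#'
#' @param config a [pipeline_config()].
#' @return invisible list with the in-memory stage results.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "vn_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$output_dir, f)
  log_stage <- function(...) message(sprintf(...))

  ## Stage: data
  if (!is.null(config$records)) {
    records <- utils::read.csv(config$records, stringsAsFactors = FALSE)
    metadata <- if (!is.null(config$metadata))
      utils::read.csv(config$metadata, stringsAsFactors = FALSE) else NULL
    cohort <- NULL
  } else {
    spec <- config$spec %||% cohort_spec()
    cohort <- simulate_cohort(spec, seed = config$seed)
    records <- cohort$records
    metadata <- cohort$metadata
  }
  log_stage("data: %d records, %d patients", nrow(records),
            length(unique(records$patient_id)))

  ## Stage: eligibility
  if (!is.null(metadata) &&
      all(c("sessions", "tests_attended", "vintage_years") %in% names(metadata))) {
    keep <- eligibility_filter(metadata)
    excluded <- setdiff(metadata$patient_id, keep)
    records <- records[records$patient_id %in% keep, ]
    metadata <- metadata[metadata$patient_id %in% keep, ]
    log_stage("eligibility: %d kept, %d excluded", length(keep),
              length(excluded))
  }

  ## Stage: variability
  yearly <- variability_summary(records, "year")
  monthly <- suppressWarnings(variability_summary(records, "month"))
  lcv_tab <- rbind(cbind(yearly, window_kind = "year"),
                   cbind(monthly, window_kind = "month"))
  utils::write.csv(lcv_tab, out("lcv_table.csv"), row.names = FALSE)
  L <- lcv_matrix(records)
  log_stage("variability: %d x %d LCV matrix", nrow(L), ncol(L))

  ## Stage: correlations
  corr <- correlation_matrix(as.data.frame(L), overrides = config$overrides)
  utils::write.csv(corr$r, out("corr_matrix.csv"))
  ut <- which(upper.tri(corr$r), arr.ind = TRUE)
  corr_long <- data.frame(var_a = corr$variables[ut[, 1]],
                          var_b = corr$variables[ut[, 2]],
                          method = corr$method[ut], r = corr$r[ut],
                          p = corr$p[ut], n = corr$n[ut])
  utils::write.csv(corr_long, out("corr_long.csv"), row.names = FALSE)
  hemo <- intersect(c("SBP", "DBP", "PR"), corr$variables)
  part <- pair_partition(corr$variables, hemo)
  sig_all <- count_significant(corr, alpha = config$alpha)
  jsonlite::write_json(list(pairs = part$counts, significant = sig_all),
                       out("pair_summary.json"), auto_unbox = TRUE,
                       digits = NA)

  ## Stage: network
  net <- build_graph(corr)
  xy <- fr_layout(net, seed = config$layout_seed)
  cent <- centralities(net)
  export_network(net, graphml = out("network.graphml"),
                 edges_csv = out("edges.csv"))
  utils::write.csv(data.frame(node = rownames(xy), xy,
                              layout_seed = config$layout_seed),
                   out("layout.csv"), row.names = FALSE)
  utils::write.csv(cent, out("centralities.csv"), row.names = FALSE)
  log_stage("network: %d nodes, %d edges", length(net$nodes), nrow(net$edges))

  ## Stage: EFA
  efa_fit <- efa(L, factors = config$n_factors)
  pa <- parallel_analysis(L, seed = config$seed)
  jsonlite::write_json(list(
    m = efa_fit$m, statistic = efa_fit$statistic, df = efa_fit$df,
    fit = as.list(efa_fit$fit),
    variance_explained = efa_fit$variance_explained,
    cumulative = efa_fit$cumulative,
    Phi = efa_fit$Phi, heywood = efa_fit$heywood,
    parallel_analysis = list(suggested = pa$suggested, kaiser = pa$kaiser)),
    out("efa_report.json"), auto_unbox = TRUE, digits = NA)
  utils::write.csv(data.frame(variable = rownames(efa_fit$pattern),
                              round(efa_fit$pattern, 4)),
                   out("efa_loadings.csv"), row.names = FALSE)
  log_stage("efa: chi^2(df) = %.1f (%d)", efa_fit$statistic, efa_fit$df)

  ## Stage: CFA
  model <- config$model %||% default_cfa_model()
  if (is.character(model)) model <- read_cfa_model(model)
  cfa_fit <- cfa(model, data = L, robust = config$robust)
  jsonlite::write_json(list(
    statistic = cfa_fit$statistic, df = cfa_fit$df, p = cfa_fit$p.value,
    fit = as.list(cfa_fit$fit), loglik = cfa_fit$loglik,
    n_free = cfa_fit$n_free,
    scaling_factor = cfa_fit$scaling_factor,
    estimates = as.list(cfa_fit$estimates), se = as.list(cfa_fit$se)),
    out("cfa_fit.json"), auto_unbox = TRUE, digits = NA)
  scores <- factor_scores(cfa_fit, L)
  log_stage("cfa: chi^2(df) = %.1f (%d)", cfa_fit$statistic, cfa_fit$df)

  ## Stage: factor-score association table
  t3 <- NULL
  if (!is.null(metadata)) {
    Mlev <- lcv_matrix(records, value = "M")
    t3 <- table3_report(scores, metadata, Mlev, alpha = config$alpha)
    utils::write.csv(t3, out("table3.csv"), row.names = FALSE)
  }

  ## Stage: invariance
  inv <- NULL
  if (!is.null(config$group_var) && !is.null(metadata) &&
      config$group_var %in% names(metadata)) {
    gvec <- metadata[[config$group_var]][match(rownames(L),
                                               metadata$patient_id)]
    if (length(unique(gvec)) == 2) {
      inv <- invariance_ladder(model, L, gvec,
                               thresholds = config$thresholds)
      means_level <- if (inv$achieved %in% c("scalar", "strict"))
        inv$achieved else NULL
      fm <- if (!is.null(means_level))
        compare_factor_means(inv, means_level) else NULL
      jsonlite::write_json(list(
        grid = inv$grid, deltas = inv$deltas, achieved = inv$achieved,
        factor_means = fm), out("invariance_report.json"),
        auto_unbox = TRUE, digits = NA, dataframe = "rows")
      log_stage("invariance: achieved %s", inv$achieved)
    }
  }

  manifest <- list(
    package = "varnet",
    version = as.character(utils::packageVersion("varnet")),
    seed = config$seed, layout_seed = config$layout_seed,
    config_hash = config_hash(unclass(config)),
    n_patients = nrow(L), n_biomarkers = ncol(L),
    n_records = nrow(records),
    stages = c("data", "eligibility", "variability", "correlations",
               "network", "efa", "cfa",
               if (!is.null(t3)) "table3", if (!is.null(inv)) "invariance"))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(list(records = records, metadata = metadata, lcv = L,
                 corr = corr, network = net, centralities = cent,
                 efa = efa_fit, parallel = pa, cfa = cfa_fit,
                 scores = scores, table3 = t3, invariance = inv,
                 manifest = manifest, cohort = cohort))
}

#' Factor-score association grid
#'
#' Correlates estimated factor scores with patient covariates and biomarker
#' mean levels: continuous covariates via the [choose_method()] rule
#' (Pearson/Spearman by marginal normality), dichotomous covariates via the
#' point-biserial coefficient with a Welch t-test p-value. Significance
#' stars: * p < 0.05, ** p < 0.01, *** p < 0.001.
#'
#' @param scores factor-score matrix (patients x factors, rownames =
#'   patient ids).
#' @param metadata per-patient covariate table (patient_id plus columns).
#' @param level_matrix optional patient x biomarker matrix of mean levels to
#'   append as covariates (column names get an `-M` suffix).
#' @param alpha significance level used for the star display only.
#' @return long data.frame: covariate, factor, method, r, p, stars.
#' @export
table3_report <- function(scores, metadata, level_matrix = NULL, alpha = 0.05) {
  ids <- rownames(scores)
  md <- metadata[match(ids, metadata$patient_id), , drop = FALSE]
  covs <- list()
  for (nm in setdiff(names(md), "patient_id")) {
    col <- md[[nm]]
    if (is.character(col) || is.factor(col)) {
      col <- factor(col)
      if (nlevels(col) != 2) next
      covs[[paste0(nm, ":", levels(col)[2], "/", levels(col)[1])]] <-
        as.numeric(col) - 1
    } else if (is.numeric(col)) {
      covs[[nm]] <- col
    }
  }
  if (!is.null(level_matrix)) {
    lv <- level_matrix[match(ids, rownames(level_matrix)), , drop = FALSE]
    for (b in colnames(lv)) covs[[paste0(b, "-M")]] <- lv[, b]
  }
  rows <- list()
  for (cv in names(covs)) {
    x <- covs[[cv]]
    ok <- !is.na(x)
    if (sum(ok) < 3) {
      warning(sprintf("covariate '%s' skipped (too few observations)", cv),
              call. = FALSE)
      next
    }
    binary <- all(x[ok] %in% c(0, 1))
    for (f in colnames(scores)) {
      y <- scores[, f]
      if (binary) {
        r <- stats::cor(x[ok], y[ok])
        pv <- tryCatch(stats::t.test(y[ok] ~ x[ok])$p.value,
                       error = function(e) NA_real_)
        meth <- "point-biserial"
      } else {
        normal_x <- !ks_normality(x[ok])$rejected
        normal_y <- !ks_normality(y[ok])$rejected
        meth <- if (normal_x && normal_y) "pearson" else "spearman"
        r <- stats::cor(x[ok], y[ok],
                        method = if (meth == "spearman") "spearman" else "pearson")
        pv <- cor_p_value(r, sum(ok))
      }
      rows[[length(rows) + 1L]] <- data.frame(
        covariate = cv, factor = f, method = meth, r = r, p = pv,
        stars = if (is.na(pv)) "" else if (pv < 0.001) "***"
                else if (pv < 0.01) "**" else if (pv < alpha) "*" else "",
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
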