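# Shared fixtures: cached cohorts (simulation is the expensive step) and
# small helper constructors.

.fixture_env <- new.env(parent = emptyenv())

## Default-panel cohort, memoised by seed.
cached_cohort <- function(seed = 1) {
  key <- paste0("coh", seed)
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- simulate_cohort(cohort_spec(), seed = seed)
  .fixture_env[[key]]
}

cached_lcv <- function(seed = 1) {
  key <- paste0("lcv", seed)
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- lcv_matrix(cached_cohort(seed))
  .fixture_env[[key]]
}

## Reduced panel spec (subset of biomarkers) for cheap simulations.
small_spec <- function(biomarkers, n_patients = 50, ...) {
  cohort_spec(n_patients = n_patients,
              loadings = hd_panel_loadings()[biomarkers, , drop = FALSE],
              hemodynamic = intersect(c("SBP", "DBP", "PR"), biomarkers),
              ...)
}

## Correlation object wrapping a given r matrix (p-values from the shared t
## approximation at a fixed n), for tests that need exact edge weights.
corr_from_matrix <- function(r, n = 334) {
  vars <- rownames(r)
  p <- r * 0
  for (i in seq_len(nrow(r))) for (j in seq_len(ncol(r)))
    p[i, j] <- if (i == j) 0 else varnet:::cor_p_value(r[i, j], n)
  structure(list(variables = vars, r = r, p = p,
                 n = matrix(n, nrow(r), ncol(r), dimnames = dimnames(r)),
                 method = matrix("pearson", nrow(r), ncol(r),
                                 dimnames = dimnames(r)),
                 tags = NULL),
            class = "vn_corr")
}

## Greedy factor matching between an estimated pattern and a truth loading
## matrix (rows aligned by name); returns, per truth factor, the estimated
## column index.
match_factors <- function(truth, pattern) {
  tru <- truth[rownames(pattern), , drop = FALSE]
  cmat <- abs(stats::cor(tru, pattern))
  perm <- integer(ncol(truth))
  for (i in seq_len(ncol(truth))) {
    j <- which(cmat == max(cmat), arr.ind = TRUE)[1, ]
    perm[j[1]] <- j[2]
    cmat[j[1], ] <- -1
    cmat[, j[2]] <- -1
  }
  perm
}
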