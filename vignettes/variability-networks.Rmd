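---
title: "Modelling biomarker-variability networks and regulatory domains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling biomarker-variability networks and regulatory domains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(varnet)
```

## The scientific model

In patients followed with frequent laboratory panels — the motivating
setting is maintenance hemodialysis, where blood chemistry is measured up
to twice a month and blood pressure at every session — the *variability* of
a biomarker within a patient carries information that its level does not.
Rising intra-individual variability is a robust marker of failing
regulation ("dysregulation") and predicts frailty and mortality even when
levels look unremarkable. varnet treats per-patient variability as the
primary observable:

* For a series of `k` measurements of biomarker `j` in patient `i`, the
  coefficient of variation uses the population SD (divisor `n`, not
  `n - 1`): `CV = pop-SD / mean`, and the analysis unit is
  `LCV = log10(CV)`. The log transform makes the marginal distributions
  approximately normal, which the downstream Pearson-based machinery
  assumes (a Kolmogorov–Smirnov check per variable decides where Spearman
  is used instead).
* Correlations *between* the LCVs of different biomarkers are read as
  proximity of the underlying regulatory mechanisms. The complete weighted
  graph over the LCVs — no edge thresholding, weights equal to the signed
  correlations — is the physiological network; a Fruchterman–Reingold
  layout with attraction proportional to `|r|` renders its cluster
  structure, and node strength (`sum |r|`), closeness and betweenness
  (path length `1/|r|`) quantify hubness.
* The cluster structure is modelled formally as a latent factor model: six
  correlated "regulatory domains" (metabolism, circulation, liver, salt,
  inflammation, protein), each loading on a specific set of biomarker
  LCVs. The measurement model is
  `LCV_i = nu + Lambda eta_i + eps_i`, `eta_i ~ N(alpha_g, Phi)`,
  `eps_i ~ N(0, Theta)`, with unit-variance, zero-mean factors in the
  reference configuration.

A group contrast (diabetic vs non-diabetic, female vs male) is then a
difference in latent factor means — but that comparison is only meaningful
if the measurement model is the same in both groups. The multi-group
ladder fits four nested models (configural, metric = equal loadings,
scalar = equal intercepts, strict = equal residual variances) and accepts
a step unless the fit degrades by `dCFI < -0.01`, `dTLI < -0.01` or
`dRMSEA > 0.015`; chi-square difference tests are reported but not used
for the decision, because at these sample sizes they flag trivial
misfit.

## What the estimators compute

**EFA.** `efa()` minimizes the maximum-likelihood discrepancy profiled
over uniquenesses (eigen-decomposition of `Psi^-1/2 S Psi^-1/2`, analytic
gradient on log-uniquenesses, 10 jittered restarts, tolerance 1e-6,
uniquenesses floored at 0.005 with a Heywood flag). The test statistic is
`T = (n - 1) F_min`; note `stats::factanal` prints the Bartlett-corrected
multiplier instead, so comparisons should be made on `F_min`. Oblique
rotation is direct oblimin (`gamma = 0`, quartimin) by gradient
projection; factors are reordered by explained variance (sums of squared
structure loadings over `p` — an oblique convention, so the per-factor
shares overlap and their sum exceeds the total communality share) and
sign-aligned. Exactly tied optima (an identity input) are canonicalized by
absorbing redundant factors into the uniquenesses.

**Factor count.** `parallel_analysis()` defaults to the common-factor
variant: eigenvalues of the reduced correlation matrix (squared multiple
correlations on the diagonal) compared against the 95th percentile of the
same quantity from random normal data. The component variant (raw
eigenvalues, Horn's rule) is available via `type = "component"`, but for
panels like this one — a strong general dimension plus five weak,
two-to-three-indicator domains — its population eigenvalues beyond the
fourth sit below the random-data thresholds, so it structurally
under-suggests; the common-factor variant is the appropriate default and
lands in the 5–8 range on simulated cohorts. The Kaiser count is reported
alongside.

**CFA.** `cfa()` minimizes the normal-theory discrepancy (with mean
structure when groups are modelled) by quasi-Newton iteration with
analytic gradients; residual variances are parameterized on the log scale,
which keeps Heywood-bound solutions well-behaved, and a damped Newton
polish guarantees the reported optimum has a scaled gradient sup-norm
below 1e-4 on interior coordinates. `T = sum_g (n_g - 1) F_g` (Wishart
convention), which reproduces the conventional RMSEA rounding at
`df (n - 1)`; the multi-group RMSEA carries the `sqrt(G)` factor. Standard
errors come from the inverse numerical information matrix (delta method
back to the natural scale for residual variances). Identification is by
unit factor variances and zero reference means — the choice that makes the
invariance-ladder df sequence (87 single group; 174/186/196/212 across
two groups) come out of pure moment counting. Start values: loadings at
half the indicator SD, residuals at half the variance, factor
correlations at zero. An optional mean-scaled robust statistic
(fourth-moment weight matrix) is available for single-group raw-data
fits. Factor scores use the regression method
`eta-hat = alpha + Phi Lambda' Sigma^-1 (x - mu-hat)`.

The default six-domain model uses 16 indicators and 18 loadings:
metabolism {BUN, Cr, K, P, UA}, circulation {SBP, DBP}, liver {AST, ALT},
salt {Na, Cl}, inflammation {WBC, Plat, Hb}, protein {TP, Alb}, plus
cross-loadings of Alb and Hb on metabolism. Published df arithmetic pins
down only the *counts* (16 and 18); the identity of the 16th indicator
and of the two cross-loadings is this package's documented choice, made to
match the strongest secondary loadings in the exploratory solution, and
any alternative can be supplied through `cfa_model()` or a text config
(`read_cfa_model()`).

**Second-order and bifactor variants.** The correlated-factors model can
be re-expressed with the six domain correlations generated by one
second-order factor (`Phi = g g' + diag(1 - g^2)`, preserving unit
first-order variances) or replaced by a bifactor structure (an orthogonal
general factor on every indicator). Both converge on data simulated from
their own parameters and are intended as structural views, not as the
default inferential model.

## The synthetic cohort generator

`cohort_spec()` + `simulate_cohort()` generate one-year longitudinal
panels whose variability structure follows the six-domain model, so every
downstream stage can be tested without patient data. The defaults encode
a realistic hemodialysis panel of 22 biomarkers (19 blood, 3 hemodynamic):

* Marginal levels and LCV targets per biomarker (e.g. SBP 150.8 ± 18.3
  mmHg, SBP-LCV −0.99 ± 0.10) and measurement schedules — twice-monthly
  (9 markers), monthly (4), bi-monthly (6), and per-dialysis-session for
  SBP/DBP/PR, whose per-patient yearly counts are drawn from a discretized
  right-skewed distribution with median 147 and IQR ≈ 118–156.
* Standardized loadings on the six domains, with entries below 0.1 set to
  zero and the sub-0.4 secondary loadings placed by domain plausibility
  (their exact column assignment is a generator choice, not an estimate).
* Factor correlations of 0.5 between metabolism and the rest and 0.35
  elsewhere — metabolism is the empirical hub — all positive, as expected
  for co-regulated systems.
* A diabetic/non-diabetic split (43%/57%) whose factor-mean offsets
  (0.049, 0.009, 0.021, 0.034, 0.005, −0.006 on the LCV scale of each
  domain's anchor indicator) plant higher metabolism and salt variability
  in the diabetic group. Offsets are stored on the LCV scale because
  that is the scale on which such contrasts are reported and is
  detectable at realistic sample sizes; they are converted to latent
  units via the anchor loading (e.g. metabolism: 0.82 x 0.14 ≈ 0.115 LCV
  units per latent SD).
* A winter-peaking cosine on blood pressure (amplitude 3.9 mmHg for SBP,
  2.4 for DBP, 0.2 for PR, peak month February), injected through
  `add_seasonal_component()`, so a paired February-vs-August contrast of
  monthly means recovers ≈ 7.8 mmHg for SBP.

Two calibration details matter when comparing simulated panels with
published marginal tables. First, an LCV *estimated* from k measurements
is a noisy, downward-biased version of the latent LCV: for normal data
the exact moments of `log10(sample CV)` follow chi-square theory
(bias `(digamma((k-1)/2) + log 2 - log k) / (2 ln 10)`, extra variance
`trigamma((k-1)/2) / (4 ln10^2)`; for session-linked markers both are
averaged over the count distribution). The default constructor absorbs
both terms — intercepts are raised by the bias and residual variances
reduced by the noise — so that the *realized* one-year LCV panel matches
the declared marginal means and SDs; `absorb_sampling_noise = FALSE`
yields the pure latent model instead. Second, a printed standardized
loading of 1.00 (DBP) implies a non-positive residual; the constructor
caps communalities so at least 2% of each marginal variance stays
residual, rescaling that loading row, and flags the affected biomarkers.

What the generator does *not* emulate: within-patient serial correlation
(measurements are i.i.d. around the patient mean — no dialysis-session
carry-over, no drift), level–variability coupling, seasonal cycles in
blood chemistry, missing visits beyond schedule jitter, and any mortality
or dropout process. Tests passing on these cohorts therefore validate
the estimators and the pipeline plumbing, not the clinical claims; real
panels have heavier tails and autocorrelated residuals, which is why the
robust (mean-scaled) statistic exists as an option.

## Numerical choices and degenerate inputs

* Zero-variance series raise a classed error rather than returning
  `-Inf` LCVs (downstream correlations cannot absorb them); windows with
  fewer than two usable measurements are omitted with a warning.
* A paired month contrast whose differences are identically zero returns
  `t = 0, p = 1`; constant non-zero differences raise a degenerate-series
  error.
* All correlation p-values use the two-sided t approximation
  `t = r sqrt((n-2)/(1-r^2))`, uniformly across Pearson, Spearman and
  point-biserial methods, and are never adjusted for multiplicity — in a
  panel where almost everything is genuinely correlated, multiplicity
  control would only mask effects.
* The KS normality check uses estimated parameters without the Lilliefors
  correction (conservative under the null); a Monte-Carlo calibrated
  variant is available.
* Layout and all simulations take explicit seeds; the pipeline manifest
  records them together with a config hash, and reruns are byte-identical.

## Problem sizes used in the test suite

The stochastic suites run at the study scale (334 patients, 22
biomarkers, ~230k records per cohort): 50 seeded cohorts for the CFA
loading-bias, factor-mean-coverage and factor-count checks, and 4–12
seeds for the cheaper distributional checks. A full pipeline run
(simulate through invariance) takes a few tens of seconds; one CFA fit
takes well under a second and a four-level invariance ladder a few
seconds.

## A short tour

```{r tour, eval = FALSE}
sp  <- cohort_spec()                     # the default 22-marker panel
coh <- simulate_cohort(sp, seed = 1)     # one-year records for 334 patients
L   <- lcv_matrix(coh)                   # patient x biomarker LCV matrix

cm  <- correlation_matrix(as.data.frame(L))
net <- build_graph(cm)
centralities(net)                        # BUN-LCV tops the strength ranking

efa(L, factors = 6)                      # ML + oblimin, Table-2-style layout
fit <- cfa(default_cfa_model(), data = L)
summary(fit)

g   <- coh$metadata$group
inv <- invariance_ladder(default_cfa_model(), L, g)
inv                                      # df 174/186/196/212, delta-fit grid
compare_factor_means(inv, "strict",
                     anchor_scale = setNames(sp$anchor$scale, sp$factors))
```

## Known limitations

* Invariance ladders support exactly two groups; the estimator declines
  finer splits rather than fitting under-powered four-group models.
* Robust scaling is single-group only; multi-group fits fall back to
  plain ML with a warning.
* No FIML for missing data: the variability stage either has a window or
  omits it, and the latent stage requires complete LCV panels.
* Factor scores are regression-method point estimates; their
  between-group comparisons should be read through the invariance
  machinery, not tested directly.
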