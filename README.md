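# varnet — variability-based physiological networks and regulatory-domain models

In patients monitored with frequent laboratory panels (the motivating
setting is maintenance hemodialysis, with blood chemistry measured up to
twice a month and blood pressure at every session), the *within-patient
variability* of a biomarker is a marker of failing regulation. varnet is
an R toolkit for the full analysis chain built on that idea:

1. **Variability.** For each patient × biomarker series, compute the
   annual mean `M` and `LCV = log10(CV)` with `CV = population SD / mean`
   (divisor *n*), over monthly or yearly windows, with the cohort
   eligibility filters (>100 dialysis sessions, >21 of 24 scheduled blood
   tests, ≥6 months vintage) and seasonal month-contrast tests.
2. **Association.** A mixed-method correlation matrix over the LCVs
   (Pearson/Spearman by marginal normality, point-biserial for
   dichotomies; two-sided t-approximation p-values, deliberately not
   adjusted for multiplicity).
3. **Network.** The complete weighted graph with edge weight `r`,
   Fruchterman–Reingold layout (attraction ∝ |r|), and strength /
   closeness / betweenness centralities (path length `1/|r|`).
4. **Latent regulatory domains.** From-scratch maximum-likelihood EFA
   with oblimin rotation and parallel analysis; a from-scratch CFA/SEM
   engine (mean structures, equality constraints, fit indices CFI / TLI /
   RMSEA / SRMR, AIC/BIC, regression factor scores, optional robust
   mean-scaled statistic; second-order and bifactor variants); and a
   two-group measurement-invariance ladder
   (configural → metric → scalar → strict) judged by
   ΔCFI < −0.01 / ΔTLI < −0.01 / ΔRMSEA > 0.015, with latent factor-mean
   contrasts at the achieved level.
5. **Synthetic cohorts.** A generator
   (`cohort_spec()` / `simulate_cohort()`) that emulates a realistic
   22-biomarker hemodialysis panel — schedules of 24, 12, 6 and ~147
   measurements/year, six correlated latent dysregulation domains, a
   diabetic subgroup with planted metabolism/salt offsets, and a
   winter-peaking blood-pressure cycle — so the whole pipeline is
   testable without patient data.

The measurement model is `LCV_i = ν + Λ η_i + ε_i` with
`η_i ~ N(α_g, Φ)` (unit-variance factors, zero reference means) and
`ε_i ~ N(0, Θ)`; the default confirmatory model has 6 correlated domains,
16 indicators and 18 loadings, giving df = 87 in one group and
174/186/196/212 along the two-group invariance ladder.

## Worked example

```r
library(varnet)

sp  <- cohort_spec()                  # default 22-marker dialysis panel
coh <- simulate_cohort(sp, seed = 1)  # 334 patients, one year of records
L   <- lcv_matrix(coh)                # 334 x 22 matrix of yearly LCVs

cm  <- correlation_matrix(as.data.frame(L))
cm
#> Mixed-method correlation matrix: 22 variables, 231 pairs
#>   methods: pearson=231

cent <- centralities(build_graph(cm))
head(cent[order(-cent$strength), ], 4)
#>    node strength closeness betweenness
#> 5   BUN     7.13    0.0147          38
#> 12    K     6.37    0.0135          14
#> 8    Cr     5.79    0.0121           0
#> 1   Alb     5.66    0.0116          14

fit <- cfa(default_cfa_model(), data = L)
fit
#> CFA fit (correlated-factors): 6 factors, 16 indicators, 1 group
#>   chi^2(df) = 130.6 (87), chi^2/df = 1.50, p = 0.00172
#>   CFI = 0.971, TLI = 0.960, RMSEA = 0.039, SRMR = 0.043
#>   AIC = -5937.4, BIC = -5750.6, logLik = 3017.7 (49 free parameters)

g   <- factor(coh$metadata$group, levels = c("non-diabetic", "diabetic"))
inv <- invariance_ladder(default_cfa_model(), L, g)
inv$grid$df
#> [1] 174 186 196 212
inv$achieved
#> [1] "strict"

compare_factor_means(inv, "strict",
                     anchor_scale = setNames(sp$anchor$scale, sp$factors))
#>         factor estimate    se     z       p    lcv
#>     metabolism  0.45735 0.130  3.52 0.00043  0.053
#>    circulation  0.12671 0.117  1.08 0.28000  0.013
#>          liver  0.16830 0.128  1.32 0.19000  0.034
#>           salt  0.50631 0.140  3.63 0.00029  0.050
#>   inflammation -0.01286 0.122 -0.11 0.92000 -0.002
#>        protein -0.00766 0.108 -0.07 0.94000 -0.001
```

Reading the output: BUN-LCV is the strongest network hub; the six-domain
model fits well (RMSEA < 0.05); the ladder accepts strict invariance
between the groups, so factor means are comparable, and the simulated
diabetic group shows significantly higher metabolism and salt
dysregulation (the `lcv` column translates the latent contrast onto the
log10-CV scale of each domain's anchor biomarker — here recovering the
planted offsets of 0.049 and 0.034 within sampling error).

`run_pipeline(pipeline_config(...))` chains every stage and writes the
artifact bundle (LCV table, correlation matrices, GraphML network,
layout/centralities, EFA/CFA JSON reports, invariance grid, factor-score
association table, and a manifest with seeds and a config hash; reruns
are byte-identical).

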