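Package: varnet
Title: Variability-Based Physiological Network and Latent Regulatory-Domain Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing intra-individual biomarker variability in
    longitudinal clinical panels. Computes per-patient log10 coefficients of
    variation (LCV) over monthly or yearly windows, builds mixed-method
    correlation matrices and weighted variability networks with force-directed
    layouts and centralities, and fits latent "regulatory domain" models:
    maximum-likelihood exploratory factor analysis with oblimin rotation,
    confirmatory factor analysis with mean structure, fit indices and factor
    scores, and multi-group measurement-invariance ladders (configural, metric,
    scalar, strict) evaluated by delta-fit-index rules. Includes a synthetic
    cohort generator that emulates a hemodialysis biomarker panel driven by six
    correlated latent dysregulation factors, so the whole pipeline is testable
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
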