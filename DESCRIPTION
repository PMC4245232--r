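Package: mediameta
Title: Causal Mediation Analysis of Animal Studies with Random-Effects Meta-Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimates, for each two-group animal study, how much of an
    experimental effect on behaviour is transmitted through a measured
    mediator (e.g. hippocampal neurogenesis assayed by BrdU or Ki67 cell
    counts) versus all other mechanisms, using a Bayesian three-variable
    mediation model (product-of-coefficients indirect effect). Per-study
    standardised estimates are pooled across studies with a random-effects
    meta-analysis using an empirical-Bayes (Paule-Mandel) between-study
    variance and Cochran's Q heterogeneity test. Includes a synthetic-data
    generator emulating multi-study animal experiments, within-group
    association (ANCOVA) diagnostics contrasted with the pooled ecological
    association, MCMC convergence diagnostics, and an end-to-end pipeline
    producing forest-table and JSON reports.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    metafor
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
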