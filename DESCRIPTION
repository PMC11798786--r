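Package: mrmediate
Title: Two-Sample Mendelian Randomization with Two-Step Mediation Analysis
Version: 0.1.0
Authors@R: person("mrmediate", "maintainers", email = "maintainers@example.org",
    role = c("aut", "cre"))
Description: Tools for two-sample Mendelian randomization on GWAS summary
    statistics and for two-step mediation analysis along
    exposure-mediator-outcome chains, motivated by molecular-trait studies of
    fatty liver disease. Provides summary-statistics input/output and allele
    harmonization, instrument selection (p-value thresholding, greedy LD
    clumping, F-statistic screening, Steiger direction filtering), the
    inverse-variance-weighted, MR-Egger, weighted-median and mode-based
    estimators with heterogeneity, pleiotropy-intercept and leave-one-out
    diagnostics, the MR-PRESSO global/outlier/distortion tests, delta-method
    mediation decomposition, and a seeded synthetic GWAS generator with known
    causal structure, pleiotropy and block LD for end-to-end verification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
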