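Package: targetmr
Title: Drug-Target Mendelian Randomization with Correlated Instruments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-sample drug-target Mendelian randomization from GWAS summary
    statistics: cis-instrument construction around target genes (p-value
    thresholding, LD pruning retaining weak correlation, instrument-strength
    metrics), correlation-adjusted inverse-variance-weighted estimation with a
    full pleiotropy-sensitivity suite (MR-Egger, weighted median, mode
    estimators, MR-PRESSO, Steiger directionality, leave-one-out),
    DerSimonian-Laird random-effects meta-analysis across cohorts, two-step MR
    mediation with product-of-coefficients bootstrap, and binary-outcome power
    calculation. Includes a summary-statistics simulator with known causal
    structure for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    metafor
Config/testthat/edition: 3
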