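Package: pathwayMR
Title: Pathway-Level Transcriptional Mendelian Randomization from Summary Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for estimating causal effects of pathway-level gene
    expression on complex traits using two-sample Mendelian randomization
    with cross-tissue cis-eQTL instruments. Implements instrument
    construction (per-gene top cis-eQTL selection across tissues, LD
    clumping, proxy substitution, allele harmonization), summary-data
    estimators (Wald ratio, inverse-variance-weighted, MR-Egger) with a
    full sensitivity and heterogeneity battery (Cochran's Q, Ruecker's Q',
    mean F statistic, I2_GX, leave-one-out, MR-PRESSO), a summary-level
    one-sample validation stage with fully-adjusted two-stage rank
    normalization, and a calibrated synthetic-data generator with known
    truth for every analysis stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    data.table,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'summary_io.R'
    'instrument_selection.R'
    'mr_core.R'
    'one_sample.R'
    'synthetic_data.R'
    'pipeline.R'
    'utils.R'
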