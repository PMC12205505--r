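Package: kinorewire
Title: Kinome Rewiring Analysis from MIB-MS and RNA-Seq Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A proteotranscriptomic pipeline for quantifying kinome rewiring
    in kinase-inhibitor resistance models. Takes kinase-level MIB-MS
    (multiplexed inhibitor bead mass spectrometry) intensity matrices and
    gene-level RNA-seq count matrices through left-censored imputation,
    empirical-Bayes moderated t-tests, negative-binomial Wald tests, time
    course z-profile K-means directional classification, and directional
    gene-set algebra, producing baseline (BL), overlapping-BL and acute
    EGFR-inhibitor (EGFRi) kinase signatures with a full exclusion audit
    trail. Ships a synthetic-data generator with known ground truth that
    emulates the structure of such studies, plus dose-response (four
    parameter logistic), survival (log-rank) and cross-omics correlation
    utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    minpack.lm,
    stats,
    survival,
    utils
Suggests:
    jsonlite,
    limma,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
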