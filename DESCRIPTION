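Package: dnbscreen
Title: Dynamical Network Biomarker Screening for Predisease States in
    Time-Course Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects early-warning signals of critical transitions in
    time-course gene expression experiments using dynamical network
    biomarker (DNB) statistics: the average standard deviation (I_s) and
    the small-sample-corrected average absolute correlation (I_r) of a
    candidate gene set, computed per experimental group and timepoint.
    Includes microarray-style preprocessing (probe collapse, per-sample
    2% trimmed-mean normalization, log2 transform), differential
    expression by two-tailed Welch tests with Benjamini-Hochberg FDR
    control intersected with a two-fold-change filter, correlation-
    distance average-linkage clustering of temporal profiles, gene-set
    overlap statistics by Fisher's exact test, and a synthetic-data
    generator that plants the variance/correlation burst and
    between-group shifts the method is designed to detect.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
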