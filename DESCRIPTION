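Package: ddctscreen
Title: Two-Stage Relative-Quantification Screening for miRNA qPCR Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: A reproducible pipeline for differential-expression screening of
    microRNA expression measured on TaqMan-style low-density qPCR array
    cards. Implements delta-Ct / delta-delta-Ct relative quantification
    against an endogenous control, quartile-based detection-flag triage of
    assays (values/nd/good/normal/low), a composite screening rule combining
    a Welch t-test with signed mean and median fold-changes, a top/medium/low
    confidence tiering of candidates, and a nonparametric Mann-Whitney
    validation stage. Includes a synthetic Ct-data generator with planted
    fold-change effects, sample loading shifts, technical noise and
    limit-of-detection censoring, so the whole pipeline is testable without
    access to raw instrument exports.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
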