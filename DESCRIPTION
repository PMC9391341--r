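Package: radsig
Title: Radiation Biodosimetry from Blood Gene-Expression Signatures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for reconstructing absorbed radiation dose from mouse blood
    transcriptomics. Ranks genes by Spearman correlation of expression with
    dose under Bonferroni control, builds up-/down-regulated gene signatures,
    reduces them to a per-sample scalar net signal (difference of group
    medians or geometric means), and fits dose-reconstruction models: a
    robust no-intercept nonlinear model D = k1*N + k2*N^2 + k3*sqrt(T) for
    multi-study microarray data (Tukey bisquare M-estimation) and a quadratic
    multiple regression with optional sex-interaction terms for qRT-PCR
    delta-Ct data. Includes qPCR Ct processing (well collapsing, delta-Ct
    against reference genes, 2^-ddCt fold changes), repeated random half-split
    validation, signature-size sensitivity analysis, and synthetic-data
    generators with known ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
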