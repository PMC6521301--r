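Package: grspipe
Title: Genetic Risk Scores for the Plasma Triglyceride Response to
    Omega-3 Supplementation
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds and evaluates unweighted genetic risk scores (GRS) of
    the plasma triglyceride response to omega-3 fatty acid
    supplementation. Covers responder classification from pre/post
    triglyceride measurements, per-SNP quality control (minor allele
    frequency, Hardy-Weinberg equilibrium testing), allele-frequency
    comparison between cohorts, odds-ratio-directed risk-allele coding,
    covariate-adjusted estimation of the share of response variance
    explained by a score, bidirectional stepwise SNP selection with
    forced covariates, and an extreme-response retrenchment sweep that
    refits the model on progressively balanced responder subsets. A
    synthetic cohort generator with planted genetic effects makes every
    stage testable without access to individual-level trial data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ggplot2,
    jsonlite,
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
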