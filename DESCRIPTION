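Package: homacut
Title: HOMA-IR Cut-Point Analysis for Metabolic Syndrome Screening
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to derive insulin-resistance scores (HOMA-IR) from
    cross-sectional survey records, classify metabolic syndrome under the
    ATPIII and IDF rule sets, post-stratify to census age-by-sex margins,
    and choose diagnostic cut-offs from weighted empirical ROC curves using
    the Youden index and the distance-to-(0,1) criteria, with percentile
    threshold tables, positive-likelihood-ratio curves, and percentile
    bootstrap confidence intervals for the AUC.  A synthetic cohort
    generator with a planted latent insulin-resistance factor provides
    ground truth for end-to-end validation of the pipeline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
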