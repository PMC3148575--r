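Package: matcirc
Title: Agreement Between Indicators of Material Circumstances
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Compares proxy indicators of household material circumstances --
    an individual-level residential property value index and census-tract
    median income -- against self-reported household income. Derives
    per-unit residential values from municipal assessment records,
    categorizes continuous indicators by quantile matching to a reference
    marginal distribution, and estimates agreement with concordance
    proportions, signed category-difference distributions, Spearman
    correlation, and overall and linearly weighted Cohen's kappa with
    large-sample or bootstrap confidence intervals. Includes
    reconstruction of kappa statistics from published marginal summaries,
    sharp bounds on the weighted kappa when extreme category differences
    are reported lumped, a latent-trait synthetic cohort generator for
    validation, and an end-to-end analysis pipeline with stratified
    sensitivity analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
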