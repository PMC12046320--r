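Package: carsx
Title: Cross-Species Response Signatures, Regulon Activity, and Hidden-Driver
    Inference for Immunotherapy Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Reusable implementation of a cross-species transcriptomic driver
    discovery pipeline for immunotherapy response cohorts: log2-CPM
    normalization, empirical-Bayes moderated two-group differential
    expression, ortholog merging and signed Z-score filtering into response
    signatures, Fisher overlap tests, joint principal-component response
    scores with ROC evaluation, Stouffer combined gene ranking,
    mutual-information regulon inference with bootstrap consensus and
    data-processing-inequality pruning, weighted-mean regulon activity,
    hidden-driver filtering (differential activity without differential
    expression), and running-sum gene-set enrichment. Ships a synthetic
    cohort generator with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    limma,
    pROC,
    fgsea
Config/testthat/edition: 3
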