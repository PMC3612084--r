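Package: drinkomics
Title: Cross-Model Transcriptome Comparison for Alcohol-Drinking and
    Immune-Activation Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for comparing bulk expression profiles across
    treatment models: detection-p filtering, variance-stabilizing
    transformation from a fitted quadratic mean-variance model, quantile
    normalization, iterated Grubbs outlier screening with sample-level
    removal, per-gene empirical-Bayes moderated-t differential expression,
    cross-study DE-overlap chi-square testing with direction concordance,
    consumption-expression Pearson correlation screening, cell-type marker
    set z-tests, and behavioral drinking summaries (totals, escalation,
    group comparisons). Includes a synthetic-data generator with planted
    ground truth so every stage is testable end-to-end without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    limma,
    jsonlite,
    withr
Config/testthat/edition: 3
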