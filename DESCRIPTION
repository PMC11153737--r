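Package: gsnSelect
Title: Edge-Biomarker Selection from Group-Specific Differential
    Correlation Networks
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds per-sample differential-correlation (delta-PCC)
    networks from gene expression data against a reference (normal)
    cohort, aggregates them into one weighted group-specific network per
    clinical group under a protein-protein interaction constraint, and
    selects a minimal set of gene-pair (edge) biomarkers for multi-group
    classification.  Feature selection proceeds in two rounds: random
    forest Gini-importance pre-screening followed by recursive feature
    elimination with cross-validation, with the number of retained edges
    chosen by a Cost-Benefit-Ratio stopping rule on the F1-score gain per
    added feature.  Includes a synthetic-data generator with planted
    group-specific co-expression rewiring for end-to-end validation, and
    a command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    MASS,
    S4Vectors,
    SummarizedExperiment,
    edgeR,
    ranger,
    pracma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
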