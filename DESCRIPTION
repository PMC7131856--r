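Package: immunopanel
Title: Targeted Immune-Oncology RNA Panel Analysis for Brain Metastases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for targeted immune-oncology RNA expression
    panels profiling the tumor immune microenvironment of brain metastases.
    Provides sequencing quality-control gating, no-template-control background
    subtraction with housekeeping-ratio normalization to nRPM units,
    empirical-Bayes moderated t-statistics for paired and unpaired contrasts,
    differential-expression calling by fold-change and p-value thresholds,
    Venn-style co-regulation overlaps, immune gene-class signature scoring with
    covariate-adjusted logistic association to primary cancer type, PCA sample
    embeddings, figure rendering, and a negative-binomial synthetic-data
    generator with planted effects for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    yaml,
    jsonlite,
    ggplot2,
    pheatmap
Suggests:
    limma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
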