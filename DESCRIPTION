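Package: ctcdyn
Title: Circulating Tumor Cell Marker Dynamics and Single-Cell Expression Pipelines
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Analysis pipelines for index-sorted circulating tumor cells (CTCs)
    profiled by two-marker (EpCAM/PSMA) flow cytometry and plate-based
    single-cell RNA-seq. Implements session-matched control normalization of
    median fluorescence intensities, imputation of negative baseline-subtraction
    artifacts, robust outlier filtering, minimum-median subpopulation
    thresholding, nonparametric longitudinal marker-dynamics testing, single-cell
    quality-control filters, Wilcoxon differential expression with Bonferroni and
    fold-change filtering, hub-gene correlation filtering against per-cell
    gene-set scores, and sequencing-library pooling arithmetic. Ships seeded
    synthetic cohort generators so every stage is testable without patient data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    methods,
    Matrix,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
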