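Package: epilock
Title: Loop-Design Two-Color Microarray Analysis of Proepicardial and
    Epicardial Differentiation Time Courses
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for dye-swapped looped two-color microarray
    time courses comparing proepicardial explant cardiomyogenesis with
    epicardial maturation. Provides hybridization design construction and
    validation (loop, round robin, bridges), GenePix-style spot-table
    ingestion with flag downweighting, within-array MA loess and
    between-array A-quantile normalization, weighted least-squares
    estimation of per-sample log2 expression over the design graph, a
    temporal Hotelling T2 polynomial test with Benjamini-Hochberg false
    discovery rate control, pairwise stage contrasts, correlation-distance
    k-means profile clustering, a divergent-template screen for genes whose
    profiles diverge between the two lineages, and a synthetic-study
    generator with per-probe ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    limma,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
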