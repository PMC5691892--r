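Package: tallsig
Title: Cross-Species Tumor Transcriptomic Signatures and Single-Sample Fit Scoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives bidirectional tumor gene signatures across mouse studies
    via gene set enrichment analysis (GSEA) leading edges, refines them against
    a T-cell development contrast to remove differentiation-stage genes, scores
    individual samples with single-sample GSEA (ssGSEA) bidirectional fit
    scores, classifies samples by fit thresholds, compares groups with
    Bartlett/ANOVA/Tukey statistics, and triages candidate leukemia subtypes
    with expression correlation matrices under exact critical-r significance.
    Ships a seeded synthetic two-species study generator with the statistical
    structure the analysis assumes, plus GCT/GMT/CLS readers and writers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    fgsea,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
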