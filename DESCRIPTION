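Package: laborproteome
Title: Amniotic Fluid Proteome Analysis of Term Labor and Plasma Biomarker Transfer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for aptamer-based proteomic profiling of term
    parturition. Implements empirical-Bayes moderated t-tests for differential
    protein abundance between women in labor (TIL) and not in labor (TNL) with
    Benjamini-Hochberg false discovery rate control and joint q-value/fold-change
    significance calls; preranked gene-set enrichment analysis with a weighted
    running-sum statistic, gene-set permutation null, normalized enrichment
    scores and permutation FDR; placental single-cell signature scoring by
    reference-standardized Z-score averaging; and transfer of an amniotic-fluid
    labor signature into maternal plasma evaluated by aggregated Z-scores,
    ROC/AUC with DeLong confidence intervals, and a leave-one-out
    cross-validated random forest with in-fold feature selection. Includes a
    synthetic-data generator that emulates the cohort structure the analysis
    assumes, so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    ranger,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    limma,
    fgsea,
    pROC,
    optparse
Config/testthat/edition: 3
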