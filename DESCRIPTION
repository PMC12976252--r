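Package: tpllprog
Title: Longitudinal Paired Single-Cell Analysis of Leukemia Progression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis toolkit for paired two-time-point (indolent vs active)
    single-cell transcriptomes of T-prolymphocytic leukemia. Implements
    permutation differential-abundance testing of tumor subclusters,
    cell-level Wilcoxon and pseudobulk negative-binomial differential
    expression, a gene-label permutation test for cross-patient DEG
    recurrence, gene-set module scores with expression-matched controls,
    percentile-rank cluster activity scores, metabolic transcript fractions,
    mixed paired/unpaired permutation comparisons, pseudotime orientation,
    and somatic short-variant retention filtering with longitudinal VAF
    trajectories. Ships a seeded synthetic cohort generator with planted
    ground truth so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    MASS,
    igraph,
    data.table,
    jsonlite,
    vcfR,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
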