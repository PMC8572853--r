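Package: phagodual
Title: Signature Scoring and Dual-Feature Phagocyte Detection for scRNA-seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested re-implementation of the quantitative core of a
    single-cell RNA-seq analysis of inflamed versus normal middle-ear mucosa:
    per-cell quality control with condition-specific feature-count and
    mitochondrial-fraction filters, total-count log normalization, highly
    variable gene selection, principal component embedding, k-nearest-neighbour
    graph clustering with Wilcoxon rank-sum marker detection, gene-signature
    scoring against expression-binned random control gene sets (the Cell
    Score), detection of non-professional phagocytes as dual-feature cells
    co-elevating a lineage and a phagocytosis score, condition-wise composition
    comparison, and a permutation-based ligand-receptor interaction screen.
    Ships a negative-binomial synthetic scRNA-seq generator that plants known
    cell types, doublets and dual-feature populations so that every stage can
    be validated against ground truth without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    igraph,
    methods,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
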