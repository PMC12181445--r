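Package: SenSkinTools
Title: Skin-Specific Cellular Senescence Gene-Set Scoring and Enrichment
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Scoring and enrichment analysis of the SenSkin skin-specific
    cellular senescence gene signature (164 up-regulated genes and one
    down-regulated gene, LMNB1) in bulk and single-cell RNA-seq. Provides
    signed gene-set containers with GMT import/export, a per-cell composite
    z-score, per-cell-type Wilcoxon contrasts between conditions,
    pseudobulk inter-gene correlation clustering with complete linkage,
    a phenotype-permutation gene set enrichment engine (enrichment score,
    NES, sign-stratified FDR), Wilcoxon rank-sum differential expression
    with natural-log fold-change and Bonferroni cutoffs, hypergeometric
    over-representation analysis, and a negative-binomial simulator of
    UV-exposed versus UV-protected skin single-cell and young versus old
    bulk designs with ground-truth senescence labels for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    S4Vectors,
    IRanges,
    SummarizedExperiment,
    SingleCellExperiment,
    e1071,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
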