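Package: SignatureOverlap
Title: Rank-Based Overlap and Directional Concordance of Differential
    Expression Signatures
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for comparing differential-expression signatures across
    studies and species: extraction of fold-change/P-value gene signatures
    from two-group log2 expression matrices, a rank-based Running Fisher
    overlap test with directional (up/up, down/down, up/down, down/up)
    quadrant statistics, a Pearson chi-square test of direction concordance
    against a 50 percent null, ortholog translation of signatures, Venn
    decomposition of a concordant gene set across up to three cell-type
    reference signatures, and Fisher/Benjamini-Hochberg gene-set
    over-representation. Includes a synthetic paired-study generator with a
    controllable latent concordance fraction so the whole pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'synthetic_data.R'
    'data_io.R'
    'diffexpr.R'
    'overlap_stats.R'
    'celltype_contribution.R'
    'enrichment.R'
    'pipeline.R'
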