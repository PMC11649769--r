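Package: pooledscreen
Title: Pooled shRNA Dropout Screen Analysis with Control-Anchored Nulls
Version: 0.1.0
Authors@R:
    person("pooledscreen", "developers", email = "pooledscreen@example.org",
           role = c("aut", "cre"))
Description: End-to-end analysis of pooled shRNA dropout (fitness) screens and
    companion assays for studying transcription-factor-dosage-driven myeloid
    leukemia models. Provides non-targeting-control (NTC) anchored count
    normalization, quantile-normalized per-shRNA log2 fold changes, alpha-RRA
    (robust rank aggregation) gene essentiality scores with permutation FDR,
    differential fold-change (DFC) classification of preferentially essential
    genes against an empirical NTC cutoff, single-cell gene-signature and
    lineage scoring along pseudotime, and a preranked GSEA over
    transcription-factor-bound genomic region sets assigned to signature genes
    by TSS windows. Includes seeded synthetic-data generators (screen barcode
    counts under exponential clone growth, signature-structured single-cell
    expression, and peak sets with planted co-binding and differential-binding
    structure) so every stage is testable with known ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
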