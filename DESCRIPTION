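Package: msciDynamics
Title: Silencing Dynamics of Meiotic Sex Chromosome Inactivation from
    Single-Cell RNA-Seq
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantifies meiotic sex chromosome inactivation (MSCI) from
    spermatogenesis single-cell RNA-seq: cell quality filtering and depth
    normalization, marker-based assignment of prophase I stages
    (pre-leptotene through pachytene spermatocytes), per-cell X-to-autosome
    expression ratios, per-gene stage trajectories normalized to the
    pre-leptotene baseline, thresholded categorization of X-linked genes
    into reduced/unaltered/increased silencing and silencing-defect
    severity classes, with exact Fisher r-by-c and rank-based tests for
    genotype contrasts. Includes a negative-binomial spermatogenesis
    simulator with planted, fully recoverable silencing ground truth so the
    whole pipeline is verifiable without access to a deposited dataset.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    Seurat
biocViews: SingleCell, Transcriptomics, GeneExpression, Sequencing
Config/testthat/edition: 3
RoxygenNote: 7.3.3
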