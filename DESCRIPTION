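Package: mitocell
Title: Mitochondrial Expression Sub-Populations and RNA Heteroplasmy in
    Single Cells
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end, re-runnable pipeline for discovering
    sub-populations of cells that diverge in mitochondrial (mtDNA)
    protein-coding gene expression from single-cell RNA-seq count
    matrices, and for characterising their mitochondrial RNA mutational
    landscape. Provides cell-level quality control (detected-gene,
    ribosomal-fraction, mtDNA-fraction and marker-doublet filters),
    PCA plus shared-nearest-neighbour community detection on the mtDNA
    gene subspace with high/low-expression (HE/LE) labelling and a
    cluster-retention statistic, negative-binomial and zero-inflated
    bimodal likelihood-ratio differential expression with BH-FDR
    control, strand-aware heterogenic variant calling from samtools
    mpileup text with coverage/strand/read-end/frequency filters, a
    permutation mutational-repertoire statistic, inherited-mutation
    classification, and a conservation-score permutation test.
    Seeded synthetic-data generators with planted ground truth
    (negative-binomial counts with dropout, strand-resolved pileups
    with planted low-frequency variants, conservation tracks) support
    validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    Matrix,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    optparse
Config/testthat/edition: 3
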