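Package: snvscreen
Title: Coupled Single-Cell Genotyping and Transcriptomics for Base-Editor Variant Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for single-cell CRISPR base-editor screens in
    which transcribed clone barcodes couple targeted single-cell DNA
    genotyping to single-cell transcriptomics. Provides probabilistic barcode
    demultiplexing from UMI counts via a three-component skew-normal mixture
    with dual posterior thresholds, consensus genotype calling over clone
    barcode groups robust to allele dropout, AUC-based nonparametric
    differential expression, diffusion-map loss-of-function scoring with
    classification of separation-of-function variants, label transfer between
    genotyped and non-genotyped datasets, and a synthetic-data generator with
    known ground truth so every stage of the pipeline is testable at desk
    scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
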