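Package: gastrukit
Title: Quantitative Analysis of Micropatterned Human Gastruloids
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the quantitative analysis of BMP4-differentiated
    micropatterned human embryonic stem cell colonies ("gastruloids") and
    their single-cell transcriptomes. Provides radial immunofluorescence
    profiling with DAPI normalization, density-map cell counting and a
    cosine spatial-overlap statistic for cell-sorting assays, single-cell
    quality control, normalization, highly-variable-gene selection,
    SNN/Louvain clustering and marker detection, cross-dataset label
    transfer with nearest-neighbor prediction scores and a randomization
    significance test for cluster compositions, gene-module scoring with
    expression-matched controls, and diffusion-map pseudotime with
    cluster transition probabilities. A synthetic-data module generates
    colony images with known centroids and labeled count matrices so the
    whole pipeline can be exercised end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    jsonlite,
    tibble,
    dplyr,
    tidyr,
    rlang,
    ggplot2,
    generics,
    readr,
    EBImage,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    tiff,
    png,
    withr,
    Seurat
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
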