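Package: colorweave
Title: Spatially Aware Color Assignment for Single-Cell Spatial Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assigns categorical colors to cell clusters in single-cell-resolution
    spatial maps so that spatially interlaced clusters receive maximally distinct
    colors. Pairwise spatial interlacement is scored on a dual-outlier-free
    k-nearest-neighbor graph and assembled into a cluster interlacement graph;
    palettes are generated by embedding that graph into CIELab or extracted from
    theme images by frequency-decay selection with farthest-point-sampling
    refinement; colors are matched to clusters by coarse-to-fine stochastic
    permutation optimization of a Frobenius graph-matching loss. Includes color
    vision deficiency simulation, multi-section integrative colorization, a
    simulation benchmark, and perceptual discernibility metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    farver,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    RANN,
    readr,
    rlang,
    tibble,
    uwot,
    withr,
    yaml,
    png,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jpeg,
    optparse,
    SingleCellExperiment,
    SummarizedExperiment,
    S4Vectors
Config/testthat/edition: 3
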