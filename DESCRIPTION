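Package: rg4llps
Title: RNA G-Quadruplex Control of FUS Liquid-Liquid Phase Separation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis toolkit for studies of RNA G-quadruplex
    (rG4) regulation of FUS liquid-liquid phase separation. Scans RNA
    sequences for quadruplex-forming G-rich (QGRS-style) motifs, performs
    transcriptome-interval enrichment analysis of rG4 regions against
    soluble- and droplet-phase FUS interactomes with permutation nulls,
    fits ligand-depletion binding isotherms to fluorescence anisotropy
    titrations and two-state van't Hoff models to circular dichroism melt
    curves, quantifies turbidity kinetics (area under the curve for
    inhibition, reversal and disaggregation assays), and segments and
    scores droplet and cell images (enrichment scores, phase diagrams,
    cytoplasmic-foci colocalization). A synthetic-data generator produces
    inputs with known ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics,
    stats,
    minpack.lm,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    EBImage,
    igraph,
    pracma,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    tiff,
    png
Config/testthat/edition: 3
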