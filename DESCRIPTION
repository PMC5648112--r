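Package: forestphylo
Title: Phylogenetic Community Structure of Forest-Dynamics Plots
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for DNA-barcode-based community phylogenetics of
    forest-dynamics plots: haplotype preparation of aligned barcode
    matrices, construction of ordinal constraint trees, pseudo-chronogram
    dating by even-spacing branch-length adjustment and by a mean-path-length
    method with age constraints, Faith's phylogenetic diversity,
    abundance-weighted mean pairwise and mean nearest taxon distances with
    tip-shuffle null models yielding net relatedness and nearest taxon
    indices, quadrat-level topography (elevation, slope, convexity) with
    five-way habitat classification, paired and correlation tests across
    trees and habitats, and a synthetic-data generator with known ground
    truth for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    seqinr,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    picante,
    phangorn,
    jsonlite,
    withr
Config/testthat/edition: 3
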