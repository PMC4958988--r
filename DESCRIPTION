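Package: hcsquant
Title: Quantitation of Cell Birth, Death and Morphology from High-Content
    Screening Images
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An image-based high-content screening (HCS) quantitation
    pipeline for heterogeneous cell populations. Segments nuclei and cell
    bodies from multi-channel fluorescence microscopy fields, classifies
    cells as live or dead from dead-cell stain intensity (absolute
    threshold or nuclear-to-background ratio), extracts single-cell
    morphology features, assigns cells to subpopulations by fluorescence
    gating or by a trained linear classifier, and decomposes live/dead
    count time series into net growth, birth and death rates under an
    exponential growth model with constant per-capita death hazard.
    Ships a ground-truthed synthetic-data generator (rendered image
    fields and exact stochastic birth-death simulation) so every stage
    is testable without real microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    EBImage,
    tiff,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
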