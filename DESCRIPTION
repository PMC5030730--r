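Package: phasedyn
Title: Multi-Scale Segmentation of Single-Channel Phase-Contrast Time-Lapse
    Images and Time-Dimensionality Reduction of Cell Population Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for high-content analysis of single-channel phase-contrast
    live-imaging plates. Implements a multi-scale intensity-thresholding
    segmentation pipeline for cells with difficult morphology (parallel
    per-scale object identification with largest-object priority, followed by
    contract/merge/relabel/expand integration into one label map per frame),
    per-object morphometry (intensity, size and shape, neighbour, and radial
    distribution feature families), and reduction of the time dimension of
    per-object features into per-well or per-condition linear-trend gradient
    signature vectors with correlation matrices. Includes a synthetic
    time-lapse plate generator with ground-truth labels for validation, and a
    command-line entry point covering the full simulate/segment/measure/reduce
    workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    igraph,
    DBI,
    RSQLite,
    yaml,
    stats,
    utils,
    grDevices,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
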