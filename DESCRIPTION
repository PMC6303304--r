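Package: trenchlapse
Title: Micro-Trench Single-Cell Time-Lapse Simulation, Tracking and Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates arrays of micro-trenches confining non-adherent cell
    lineages, renders defocused phase-contrast and death-marker fluorescence
    movies with ground truth, and provides the full analysis chain for such
    assays: Laplacian-of-Gaussian spot detection after flat-field and local
    contrast correction with minimum-error thresholding, per-trench linear
    assignment tracking with gap closing and division detection, extraction
    of division and death events, and the downstream statistics (cycle-time
    distribution fits, sister-cell correlations, time-to-death densities,
    cell-cycle-phase correlation and four-parameter logistic dose-response).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    igraph,
    fitdistrplus,
    minpack.lm,
    yaml,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
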