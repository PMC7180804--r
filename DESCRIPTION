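Package: foascope
Title: Fiber-Optic-Array Microscope Image Analysis for Yeast Viability
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for live/dead yeast cell counting in micrographs taken
    through a tapered fiber optic array (FOA). Provides a synthetic
    micrograph generator that emulates the FOA's hexagonal core/gap lattice
    and uneven illumination with known cell ground truth, contrast-limited
    adaptive histogram equalization (CLAHE) preprocessing that suppresses
    the fiber-gap artifact, hexagonal scan-window detectors for unstained
    (live) and methylene-blue stained (dead) cells, minimum-size particle
    counting, detection-to-ground-truth matching with cluster exclusion,
    k-fold threshold cross-validation, and closed-form tapered-fiber optics
    calculations (normalized frequency, reflection angles, evanescent
    penetration depth, lattice packing and resolution).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    grDevices,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr
Suggests:
    igraph,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
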