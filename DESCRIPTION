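Package: ionrad
Title: Single-Ion Helium Radiography: Simulation, Event Building and Image Quality
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale model of a five-layer pixel-detector system for single-ion
    helium radiography. Transports ions through a step phantom with a parametric
    CSDA energy-loss and Highland multiple-scattering model, renders sparse
    per-layer pixel frames with realistic cluster signals and detector artifacts,
    and provides the full processing chain: frame decoding, connected-component
    cluster analysis, per-pixel energy calibration and partial-depletion
    recalibration, artifact cleaning, detector alignment, single-ion tracking and
    front/rear track matching, helium/hydrogen identification, mid-plane
    radiograph formation, and contrast-to-noise and oversampled-edge MTF image
    quality metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    generics,
    igraph,
    MASS,
    signal,
    readr,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    tiff,
    jsonlite,
    optparse
Config/testthat/edition: 3
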