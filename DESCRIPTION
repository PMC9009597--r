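Package: ehttrack
Title: Contractility Analysis of Engineered Heart Tissues from Bright-Field Video
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automatic analysis of engineered heart tissue (EHT) contractility from
    high-speed bright-field TIFF stacks. Tracks the centroids of the two elastic
    pillars anchoring the tissue (black-tip thresholding or maximally stable
    extremal region detection for transparent pillars), converts pillar deflection
    into contraction force via the elastic beam bending equation, segments the
    tissue to obtain its projected surface area and the axial stress (force per
    surface area), and extracts per-beat contraction kinetics (10%/90% contraction
    and relaxation times, velocities). Includes a batch driver with per-file and
    summary outputs, and a synthetic bright-field video generator with analytic
    ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    jsonlite,
    tiff,
    signal,
    stats,
    grDevices,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse,
    withr
Config/testthat/edition: 3
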