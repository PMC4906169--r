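Package: golgiring
Title: Quantitative Fluorescence Microscopy of Cellulose Synthase Trafficking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis tools for quantitative live-cell and
    electron microscopy of cellulose synthase complex (CSC) trafficking.
    Classifies Golgi bodies as ring-shaped or solid from cross-sectional
    intensity profiles, estimates object diameters by constrained
    double-Gaussian fitting, scores plasma-membrane CSC insertion events in
    post-bleach time-lapse movies and converts them to delivery rates,
    detects and links fluorescent foci to estimate migration speeds,
    computes Manders co-localization coefficients, and quantifies
    immuno-gold particle positions along the Golgi axis. Every analysis is
    paired with a seeded synthetic-data generator with known ground truth
    for parameter-recovery validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    withr,
    minpack.lm,
    EBImage,
    tiff,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
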