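Package: dnacurtains
Title: Simulation and Analysis of Single-Molecule DNA Curtain Experiments on
    Modified Lambda DNA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for single-molecule DNA curtain studies of engineered
    bacteriophage lambda substrates. Models the 48.5-kb linear substrate with
    insertion cassettes and nicking/restriction sites and predicts digestion
    products; generates synthetic binding positions, one-dimensional sliding
    trajectories, dwell times and rendered TIFF image stacks from named
    experiment presets; detects and localizes particles by two-dimensional
    Gaussian fitting and links them into trajectories; and analyzes the
    results with binding-position histograms and Gaussian peak fits, bootstrap
    errors, windowed enrichment statistics, mean-squared-displacement
    diffusion estimation, encounter-behavior classification and censored
    exponential dwell-time survival fits.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    graphics,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils
Suggests:
    mclust,
    survival,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
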