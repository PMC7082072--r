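Package: conemosaic
Title: Cone Photoreceptor Mosaic Patterning: Synthetic Data, Segmentation,
    Profiling, and Hybrid Stochastic Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying and modeling the dorsal-ventral patterning of
    S- and M-opsin expression in the mouse cone photoreceptor mosaic. Provides a
    ground-truth synthetic retina generator (cell tables and rendered two-channel
    image tiles), an active-contour segmentation pipeline for two-channel
    fluorescence tiles, per-cell profiling (classification, Hill-transition fits,
    retina alignment, joint intensity distributions, density-based clustering,
    transition statistics), a hybrid multiscale simulator coupling a deterministic
    thyroid-hormone diffusion field to per-cell stochastic fate and expression
    networks sampled with Gillespie's algorithm, and calibration and comparison
    utilities for fitting the simulator to mean-retina target curves.
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
    ggplot2,
    readr,
    jsonlite,
    withr,
    generics,
    stats,
    utils,
    class,
    minpack.lm,
    tiff,
    EBImage
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
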