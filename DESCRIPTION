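Package: afmdfs
Title: Dynamic Force Spectroscopy Analysis of AFM Force-Distance Curves
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing atomic force microscopy (AFM) single-molecule
    force spectroscopy experiments: reading and pre-processing force-distance
    curves, detecting adhesion (bond rupture) events on retraction segments,
    building adhesion-force distributions and force-volume adhesion maps,
    fitting contact-time interaction kinetics, and estimating energy-landscape
    parameters (equilibrium force, thermal force, dissociation rate, barrier
    width, binding free energy, bond lifetime) with the Friddle-Noy-de Yoreo
    two-regime bond-rupture model. Includes a stochastic first-passage
    bond-rupture simulator and force-curve/force-volume generators with known
    ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    ggplot2,
    graphics,
    generics,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
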