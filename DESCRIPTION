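Package: vesicledrop
Title: Brownian Settling Bias in AFM Sizing of Extracellular Vesicles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to quantify how Brownian motion inside a sample drop biases
    atomic force microscopy (AFM) size measurements of extracellular vesicles.
    Provides a Monte Carlo simulator of vesicle diffusion and first-contact
    attachment to the substrate (Einstein-Stokes diffusion, absorbing bottom,
    reflecting drop surface), an AFM height-image analysis pipeline that
    detects vesicle blobs, filters them by profile asymmetry, fits circles to
    spherical-cap cross-sections and converts cap geometry to free-floating
    geometric diameters, log-normal scale/shape fitting with bootstrap
    confidence intervals linking geometric (AFM) and hydrodynamic (NTA)
    diameters, and a synthetic-data generator producing both input classes
    with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
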