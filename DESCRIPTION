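Package: cryofit
Title: Model Building, Fitting and Restrained Refinement for Cryo-EM Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for interpreting electron cryo-microscopy reconstructions
    with atomic models: randomized rigid-body docking ("jiggle" fitting),
    fragment-based model morphing, helix finding and orientation, fold
    screening with contrast scoring, nucleic-acid base-pair and stacking
    restraint generation, robust (Geman-McClure) restrained coordinate
    refinement in real or reciprocal space, Fourier shell correlation
    metrics including the shell-count-weighted FSC average, map sharpening
    and amplitude scaling, and half-map cross-validation of overfitting.
    A synthetic-density module (five-Gaussian electron scattering factors,
    band-limited model maps, independent-noise half-map pairs, ideal
    helix and nucleic-acid duplex generators) lets every workflow be
    exercised on generated fixtures without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    withr,
    knitr
Config/testthat/edition: 3
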