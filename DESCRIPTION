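Package: prfmapr
Title: Population Receptive Field Retinotopic Mapping with a Synthetic Cortex
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Forward-model population receptive field (pRF) analysis for
    visual-field mapping experiments: binary stimulus-aperture movies for
    rotating-wedge, expanding/contracting-ring and full-field designs,
    per-subject two-gamma hemodynamic response function estimation, Gaussian
    pRF fitting by coarse-to-fine search, retinotopic map summaries and
    visual-field coverage, and a scotoma-masked control stimulus model. A
    synthetic-cortex generator produces ground-truth retinotopic vertex
    populations and noisy BOLD time series, including simulated cortical
    scotomas, so the whole pipeline can be exercised and validated without
    scanner data. Companion behavioral computations cover a computerized
    perimetry screen, a binomial Bayes-factor blindsight test, adaptive
    psychophysical staircases and a robust (MAD-filtered) illusion-strength
    estimator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    RNifti,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
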