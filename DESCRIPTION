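Package: holophase
Title: Untrained-Network Phase Retrieval from Single-Shot Lensless
    Diffraction Patterns
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative phase imaging from a single in-line (lensless)
    coherent diffraction pattern. A randomly initialized convolutional
    encoder-decoder network is optimized against a differentiable
    angular-spectrum diffraction model so that the intensity predicted from
    its output phase matches the measured intensity; no training data or
    ground-truth phases are required (the deep-image-prior principle,
    anchored by the physics of free-space propagation). Includes classical
    baselines (multi-plane Gerchberg-Saxton, a spectral transport-of-
    intensity solver, and regularization by denoising with a pluggable
    denoiser), a synthetic phase-phantom test bed, range-rescaled mean
    square error evaluation, and TIFF plus sidecar-JSON input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    Rcpp,
    stats,
    tiff,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    png,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
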