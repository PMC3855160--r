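Package: StereoEnergy
Title: Binocular Energy-Model Disparity Estimation with Log-Gabor Filter Banks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Position-shift binocular energy model of primary visual cortex
    (V1) complex cells for stereo disparity estimation. Builds log-Gabor
    (and baseline Gabor) quadrature filter banks in the frequency domain,
    computes push-pull rectified simple-cell and phase-invariant complex-cell
    responses over a set of positional-disparity hypotheses, selects per-pixel
    disparities coarse-to-fine by local-extremum tracking across spatial
    frequencies, and pools orientation/frequency channel maps by iterative
    robust averaging. Includes seeded random-dot stereogram generators
    (square, ramp and Gabor-surface depth profiles) with ground truth,
    bad-pixel and root-mean-squared-error evaluation metrics with border
    exclusion, batch Monte-Carlo evaluation, PFM/PGM/PNG/TIFF disparity and
    image input/output, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    Rcpp,
    png,
    tiff,
    yaml,
    jsonlite,
    optparse
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'StereoEnergy-package.R'
    'filterbank.R'
    'energy.R'
    'search.R'
    'pooling.R'
    'stereogram.R'
    'evaluation.R'
    'pipeline.R'
    'io.R'
    'cli.R'
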