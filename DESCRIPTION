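Package: radiosem
Title: Semantic Representation Learning for Contactless Radio Cardiac Monitoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for radio-based contactless cardiac monitoring built around a
    semantic representation of the cardiac cycle. The package simulates coupled
    ECG and frequency-modulated continuous-wave (FMCW) radar measurements driven
    by one shared latent cardiac state, converts raw radar cubes into a 4D
    spatiotemporal cardiac-motion tensor (voxel beamforming, phase demodulation,
    respiration suppression), pretrains a beta-VAE ECG semantic space, learns an
    aligned radio representation via intra-modal semantic-invariant compression
    and cross-modal alignment, and provides interpretable linear semantic
    readouts (ventricular rate, PR, QT), linear arrhythmia diagnosis (atrial
    fibrillation, premature beats), heart-rate-variability analysis, and a
    subject-disjoint cross-validated evaluation protocol with bootstrap
    confidence intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    signal,
    jsonlite,
    yaml,
    withr,
    nnet
Suggests:
    testthat (>= 3.0.0)
LinkingTo:
    Rcpp,
    RcppArmadillo
Config/testthat/edition: 3
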