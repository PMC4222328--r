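Package: mmnpipe
Title: Sensor-Space Mismatch-Negativity Analysis Pipeline with Synthetic EEG
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for sensor-space analysis of auditory mismatch-negativity
    (MMN) oddball experiments: generation and validation of oddball trial
    sequences, simulation of continuous multichannel EEG with known
    ground-truth condition effects, an ERP preprocessing chain (zero-phase
    band-pass filtering, decimation, EOG derivation, correlation-based
    screening of linear signal components, spherical-spline channel
    interpolation, epoching, baseline correction, amplitude/jump artifact
    rejection), plus-minus (polarity-flip) signal-to-noise quality control
    with participant exclusion rules, region-of-interest window-mean 2x2
    repeated-measures ANOVA with planned comparisons, and a cluster-mass
    permutation test on electrode-plane x time volumes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
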