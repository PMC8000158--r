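Package: ecgibench
Title: Torso-Signal Processing Effects on Epicardial Potential-Based ECGI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Evaluation pipeline for the effect of torso-signal processing on
    epicardial potential-based electrocardiographic imaging (ECGI). Generates
    torso-tank-like synthetic datasets (paced epicardial electrograms projected
    to a torso surface through a boundary element method volume-conductor model
    and contaminated with power-line interference, broadband channel noise and
    baseline wander), implements a 49-variant filter bank (seven high-frequency
    removal methods, five baseline-drift removal methods, their 35 combinations,
    raw, and PCA-based signal averaging), reconstructs epicardial potentials by
    zero-order Tikhonov regularization with L-curve corner selection and median
    lambda pooling, and quantifies electrogram and activation-map accuracy
    (SNR-HF, baseline shift, amplitude differences, QRS correlation, activation
    times, pacing-site localization error).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    jsonlite,
    methods,
    signal,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
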