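Package: sleepfusion
Title: Multimodal Sleep Staging with Hilbert-Huang Features and Deep Fusion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automatic sleep stage classification from EEG and EOG
    polysomnography. Thirty-second epochs are transformed with empirical mode
    decomposition and Hilbert spectral analysis into time-frequency images,
    fed to two heterogeneous subnetworks (a 3D convolutional network for EEG
    sub-segment stacks and an LSTM for the EOG spectral sequence) trained with
    class-balanced focal loss, and fused by a Gaussian-Bernoulli deep belief
    network pretrained with contrastive divergence and fine-tuned with
    cross-entropy. Includes EDF/EDF+ reading and writing, a synthetic
    polysomnography generator with stage-dependent spectra and realistic
    stage-transition dynamics, and a subject-wise cross-validation and
    scoring harness (accuracy, Cohen's kappa, per-class F1).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    signal,
    jsonlite,
    stats,
    tools,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    MASS
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
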