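Package: clrnet
Title: Motor Imagery EEG Decoding with a CNN-BiLSTM Network with
    Cross-Layer Residual Connections
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end decoding of four-class motor imagery
    electroencephalography (left hand, right hand, foot, tongue). Implements
    the CLRNet architecture: a four-layer convolutional front-end feeding
    five bidirectional LSTM blocks whose outputs are combined by
    ResNet-style cross-layer sums before a softmax head. Ships the full
    preprocessing chain used with BCI Competition IV dataset 2a style
    recordings (8-30 Hz zero-phase Butterworth filtering, EOG channel
    removal, cue-locked epoch extraction, five-level wavelet-packet
    decomposition with frequency-ordered Mu/Beta node reconstruction and
    resampling), a minimal GDF reader, a paradigm-faithful synthetic ERD/ERS
    EEG simulator for testing without data downloads, and a per-subject
    training and evaluation harness with ablation and channel-subset
    experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
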