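Package: ciacnet
Title: Dual-Branch Convolutional Attention Network for Motor-Imagery EEG Decoding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a compact convolutional architecture for motor-imagery
    EEG classification: two parallel EEGNet-style convolutional branches
    (temporal, depthwise spatial and pointwise temporal convolutions with
    batch normalization, ELU, average pooling, dropout and ridge weight
    penalties), a channel/spatial attention block that augments the usual
    average and max pooling with stochastic pooling, a dilated causal
    temporal convolutional network with residual blocks, and multi-level
    feature concatenation into a softmax classifier. Training (Adam,
    categorical cross-entropy, learning-rate reduction on plateau, early
    stopping and best-weight checkpointing), Cohen's kappa and confusion
    matrix evaluation, a synthetic motor-imagery EEG generator with
    class-dependent band-power modulation, Z-score normalization, EDF
    epoching and a command-line interface are included. All layers and
    their gradients are implemented in R with C++ convolution kernels.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
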