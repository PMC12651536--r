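Package: tastenet
Title: Multi-Branch Strip-Convolution Attention Networks for Taste EEG Decoding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies multichannel electroencephalography (EEG) epochs evoked
    by gustatory stimulation into stimulus concentration classes. Implements a
    lightweight feature-computation block that combines multi-branch strip
    convolutions (1xk along time, kx1 across electrodes), channel and spatial
    attention gates, scaled dot-product self-attention over learned channels,
    and residual connections, assembled into a compact classification network
    with a point-wise expansion head, temporal pooling and a dense classifier.
    Ships a parametric synthetic taste-EEG generator (class-dependent evoked
    amplitude, spatial spread and onset latency over 1/f background noise), a
    stratified training / k-fold cross-validation harness with confusion-matrix
    metrics, and ablation grids over kernel directions, branches and block
    components. All learned layers run on a compiled forward/backward core;
    results are returned as tibbles with broom-style tidiers and ggplot2
    autoplot methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    signal,
    tibble,
    dplyr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
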