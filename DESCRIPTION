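Package: spikehist
Title: Event-Driven Spiking Convolutional Networks with Histogram-Trained
    Classifiers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates event-driven (address-event representation) spiking
    convolutional networks with signed leaky integrate-and-fire neurons and
    linear leakage, and trains their fully-connected spiking classifier layer
    in the frame domain: spike trains are run through a fixed Gabor feature
    extraction layer, spike-count histograms collected at the flatten stage
    are used to fit a bias-free softmax classifier by mini-batch stochastic
    gradient descent, and the learned weights are integer-scaled back onto
    spiking neurons. Includes Poisson and intensity-to-latency image encoders,
    synthetic oriented-bar and DVS-like event fixtures, sample-by-sample and
    one-pass presentation modes, and evaluation metrics (classifier loss,
    first-spike latency, event activity, accuracy versus input fraction,
    Wilson confidence intervals, leave-one-out cross-validation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    yaml
Config/testthat/edition: 3
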