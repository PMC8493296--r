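Package: plasticsnn
Title: Differentiable Synaptic Plasticity for Spiking Neural Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Spike-response-model neural networks whose synaptic weights and
    plasticity rules are learned jointly by surrogate-gradient backpropagation
    through time. Implements differentiable Hebbian trace dynamics (linear
    decay, Oja's rule, BCM with a sliding threshold) and their learned
    neuromodulated variants, a noisy cue-association T-maze benchmark with
    population spike input, place-coded observation encoding and spiking
    action decoding for continuous control, REINFORCE and clipped-surrogate
    policy-gradient training with Adam, and a command-line experiment runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    generics,
    jsonlite,
    yaml,
    ggplot2
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
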