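Package: rsnn
Title: Recurrent Spiking Neural Networks with Adaptive Thresholds and
    Reward Propagation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and training of recurrent spiking neural networks
    built from two-channel leaky integrate-and-fire neurons whose firing
    threshold adapts to the neuron's own spike history. Hidden layers carry
    sparse random recurrent connections. Training uses either a global
    reward-propagation rule, in which the repeated one-hot label is projected
    through a fixed random feedback matrix directly to every hidden layer, or
    a layer-by-layer surrogate-gradient rule with a boxcar pseudo-derivative.
    Includes a deterministic synthetic spectrogram generator, a uniform-noise
    corruption operator, a noise-robustness evaluation protocol and a dense
    non-spiking baseline for comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
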