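Package: astrosim
Title: Spiking Neuron and Astrocyte Network Simulation with
    Dopamine-Modulated Reinforcement Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates spiking neural networks in which both neurons and
    astrocytes are expressed in the Izhikevich two-variable dynamical
    framework. Astrocytes are parameterised to reproduce the approximately
    linear current-voltage relationship of glial cells and do not spike
    under physiological currents. Synaptic, IP3, potassium and glial
    glutamate signalling pathways are modelled as superpositions of
    alpha-function kernels, allowing bipartite (neuron-neuron) and
    tripartite (astrocyte-coupled) synapses to be compared within one
    network architecture. Includes a dopamine-modulated reinforcement
    learning rule driven by reward-prediction error, a winner-take-all
    stimulus classification experiment with Gaussian receptive-field
    encoding, matched-seed comparisons of the two architectures, and
    noise-robustness sweeps. Steady-state current-voltage analysis and
    mean-squared-error parameter fitting are provided for single cells.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    graphics,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
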