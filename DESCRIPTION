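Package: recipronet
Title: Balanced Cortical Network Simulation with Controlled Synaptic Reciprocity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a strongly recurrent, balanced network of excitatory and
    inhibitory conductance-based spiking neurons modelled on layer 2/3 of rodent
    primary visual cortex, with a wiring rule that sets the probability of
    reciprocal (bidirectional) connections independently of the in-degree
    distribution. Includes orientation-tuned feedforward drive with quenched
    disorder, stochastic background input, and a full spike-train statistics
    suite: orientation selectivity index, Fano factor, inter-spike-interval
    coefficients of variation (CV, CV2), Spearman serial rank correlations with
    the renewal and non-renewal count-variance identities, spike-train
    autocorrelation functions and decorrelation times. Synthetic point-process
    generators (Poisson, gamma renewal, Markov-correlated, periodic,
    rate-modulated) provide independent oracles for every statistic.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Matrix,
    data.table,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
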