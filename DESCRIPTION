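Package: idipnet
Title: Spiking Network Models of Input-Dependent Inhibitory Plasticity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Clocked simulation of conductance-based leaky integrate-and-fire
    networks under input-dependent inhibitory plasticity (IDIP), a
    network-centered homeostatic rule in which each inhibitory neuron scales
    its outgoing synapses by the difference between a low-pass filtered record
    of its excitatory synaptic input and a target value. Ships two ready-made
    models: a hippocampal CA3-to-CA1 place-cell circuit with Hebbian plus
    homeostatic feedforward plasticity (exploration, optogenetic-style
    silencing and consolidation protocols) and a sparse random recurrent
    network with lognormal weights (stabilization, connectivity sweeps,
    subset drive, firing-rate-rank and associative-memory protocols), along
    with the neuron-centered inhibitory STDP rule as a baseline, IDIP rule
    variants, multi-seed ensemble running, and text-based recorders.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml,
    jsonlite
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
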