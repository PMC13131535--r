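Package: glifcolumn
Title: Differentiable Simulation and Training of Cortical Column Spiking Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds biologically parameterized cortical-column networks of
    generalized leaky integrate-and-fire (GLIF3) point neurons with after-spike
    currents and double-alpha synaptic kinetics, simulates them at 1 ms
    resolution, and trains recurrent and background synaptic weights by
    backpropagation through time with a triangular surrogate spike gradient and
    a sign-preserving multiplicative (Exponentiated Adam) optimizer. Includes
    construction rules for distance-, orientation- and in-degree-dependent
    connectivity, log-normal synaptic weight sampling, Yule-Simon thalamic
    synapse counts, a parametric surrogate LGN front end, a multi-objective
    physiological training loss (quantile-Huber firing-rate matching,
    crowd-surrogate orientation/direction selectivity, multi-scale Fano factor
    synchrony, voltage and Wasserstein-1 weight regularizers), and a post-hoc
    analysis suite (selectivity indices, preferred directions, like-to-like
    wiring statistics, outgoing-weight cohorts, and silencing perturbations).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    minpack.lm,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
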