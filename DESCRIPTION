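Package: casynapse
Title: Calcium-Based Synaptic Plasticity and Memory Time Scales
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Event-based stochastic simulation of a calcium-based model of
    synaptic plasticity together with the analytic theory of memory decay
    under background activity. Postsynaptic calcium is a shot-noise process
    driven by pre- and postsynaptic spikes; the synaptic efficacy undergoes
    threshold-gated potentiation, depression and noise, optionally shaped by
    a double-well potential. The package provides exact event-based
    propagation of single synapses and ensembles, the stationary calcium
    probability density (closed form and numeric master-equation solver),
    the truncated Ornstein-Uhlenbeck theory of exponential efficacy decay,
    effective-potential and Kramers escape analysis of bistable synapses, a
    scaled-down recurrent network of leaky integrate-and-fire neurons with
    plastic excitatory synapses, and the self-consistent mean-field solution
    of its steady state.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    pracma,
    minpack.lm,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
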