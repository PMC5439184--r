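Package: famlsm
Title: Familiarity Detection in Spiking Liquid State Machines with
    NMDAR-Dependent Bidirectional Plasticity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates recurrent reservoirs of leaky integrate-and-fire
    neurons whose excitatory synapses carry an NMDA-receptor plasticity
    model based on the calcium control hypothesis: back-propagating action
    potentials and EPSPs drive a voltage-dependent calcium current, and the
    synaptic calcium concentration sets the direction and rate of weight
    change, unifying rate-based LTP/LTD with spike-timing-dependent
    plasticity. Includes image-to-spike-train encoding, synthetic face-like
    stimulus generation, baseline-normalization and three-phase familiarity
    experiment protocols, and analyses of the resulting memory traces:
    Fisher discriminant ratios on spike counts, potentiated-subnetwork
    extraction, clustering coefficients and critical-neuron overlap.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    png,
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
RoxygenNote: 7.3.3
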