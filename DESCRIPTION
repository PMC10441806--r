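Package: astronet
Title: Effective Astrocyte Ensheathment in Balanced Spiking Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Two-scale modelling toolkit for astrocyte ensheathment of
    synapses. A microscale Monte-Carlo simulator of neurotransmitter
    diffusion in an idealized synaptic cleft with partially absorbing,
    recharging receptors and an absorbing astrocyte boundary (the
    diffusion-with-recharging-traps model) quantifies how astrocyte
    protrusion makes synaptic transmission weaker and faster. The derived
    linear mapping is applied as an "effective astrocyte" to heterogeneous
    balanced networks of exponential integrate-and-fire neurons, with
    non-spatial and spatially extended (torus) connectivity, shared
    Gaussian-process or Poisson feedforward drive, and the analyses
    (synchrony classification, pairwise spike-count correlations, shared
    current decomposition) used to study ensheathment-driven loss of
    excitation-inhibition balance.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    graphics,
    jsonlite,
    stats,
    tibble,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
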