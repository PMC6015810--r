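Package: polybind
Title: Polychronization and Feature Binding in Spiking Neural Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Conductance-based leaky integrate-and-fire network simulator
    with randomized axonal conduction delays and trace-based spike
    timing-dependent plasticity (STDP), modelling the emergence of
    polychronous neuronal groups and feature-binding circuits in a
    hierarchical model of the primate ventral visual pathway. Includes
    Gabor-filter encoding of visual stimuli into Poisson spike trains,
    single-cell and spike-pair information analyses, first-spike
    precision statistics, delay-consistent binding-circuit detection,
    and reproducible experiment drivers for two-layer and four-layer
    architectures.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
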