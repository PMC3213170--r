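Package: stpnet
Title: Dynamically Reorganizable Attractor Networks with Short-Term Synaptic Plasticity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of a prefrontal-cortex-style attractor network
    whose cell assemblies are reorganized on the fly by short-term synaptic
    plasticity, producing an endogenous switch from goal representation to action
    representation during a delay period. Provides a conductance-based leaky
    integrate-and-fire spiking network with Tsodyks-Markram facilitating,
    depressing and constant synapses (compiled core), a deterministic mean-field
    reduction with Naka-Rushton firing-rate transfer functions fitted to the
    spiking neurons, fast-slow stability analysis that tracks attractor formation
    and destruction by Newton-Raphson equilibrium finding and eigenvalue
    classification, and the derived measures used to characterise representational
    switching: principal-component state-space projections, dummy-variable
    regression selectivity time courses, transition-time detection, batch
    statistics, and reproducible experiment protocols with parameter sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    deSolve,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
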