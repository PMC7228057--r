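Package: metaLV
Title: Persistent Fluctuations in Random Lotka-Volterra Metacommunities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and theory for high-diversity generalized
    Lotka-Volterra metacommunities with quenched random interactions,
    migration between patches and an all-patch extinction cutoff.
    Provides a fast adaptive integrator for the deterministic dynamics,
    samplers for the quenched disorder, the dynamical mean-field
    (representative metapopulation) self-consistent theory that predicts
    the statistics of the fluctuating states, and the observables used to
    characterise them: diversity, fluctuation strength and correlation
    kernels, source/sink persistence, linear stability of fixed points,
    and extinction-time scaling exponents.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml,
    pracma,
    withr
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
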