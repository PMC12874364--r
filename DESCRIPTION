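Package: slmassembly
Title: Cluster-Mediated Lattice Self-Assembly Simulation and Stochastic
    Landscape Forecasting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simulates cluster-mediated self-assembly of distinguishable
    particles on a two-dimensional periodic lattice with multi-target memory,
    directed or undirected specific interactions, single-particle and
    virtual-move Monte Carlo dynamics, and a nonequilibrium self-healing drive
    on internal particle states. Provides the stochastic landscape method for
    forecasting the remaining time to first assembly from segmented energy
    trajectories, together with ensemble variability metrics (survivor-average
    RMSD, first-assembly-time spread and distribution fits) that quantify
    predictability.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    tibble,
    dplyr,
    purrr,
    rlang,
    stats,
    generics,
    ggplot2,
    fitdistrplus,
    jsonlite,
    readr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
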