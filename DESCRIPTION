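Package: adaptrate
Title: Dynamic Adaptive Learning-Rate Analysis for Change-Point Tasks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for studying how learners adapt
    their learning rate in volatile environments. Generates magnitude- and
    probability-learning observation sequences from hazard-rate change-point
    processes, runs the normative Bayesian observers (a reduced Gaussian
    change-point model and a grid-based Bernoulli Bayesian filter) that define
    change-point probability and prior uncertainty, simulates subject-like
    agents (delta rule, normative, report noise, learning noise), and provides
    the downstream analyses: per-observation apparent learning rates,
    change-point-aligned dynamics with cluster-based permutation testing,
    two-determinant regression of the learning rate on change-point
    probability and prior uncertainty, estimate-accuracy calibration, and a
    bias/variance decomposition of group estimation error with bootstrap
    standard errors.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
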