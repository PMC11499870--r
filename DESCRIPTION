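Package: podrift
Title: Preferred-Orientation Drift Analysis and Hebbian-Volatility Plasticity Modelling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying representational drift of orientation tuning
    in chronic calcium-imaging experiments and for simulating its synaptic basis.
    Provides a seeded generator of trial-structured synthetic two-photon
    experiments with known ground-truth tuning; vector-sum estimation of
    preferred orientation with bootstrap confidence intervals and
    responsiveness/tunedness criteria; drift, convergence and shuffle-null
    statistics including pairwise-signal-correlation similarity decay; and a
    two-layer feedforward network model in which synaptic weights evolve under
    a Hebbian term plus activity-independent volatility, scaled by a
    weight-dependent propensity function and constrained by daily divisive
    normalization.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    minpack.lm,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
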