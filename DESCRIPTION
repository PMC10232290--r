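Package: microdcm
Title: Conductance-Based Microcircuit Dynamic Causal Modelling with
    Parametric Empirical Bayes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates and inverts a six-population conductance-based
    canonical microcircuit model of source-level evoked magnetoencephalography
    responses (standard and deviant conditions of an auditory oddball
    paradigm). Single-subject inversion uses variational Laplace with a
    decomposable free energy; a parametric empirical Bayes second level
    relates laminar- and receptor-specific synaptic gains to a per-subject
    scalar covariate such as a synaptic-density measure. Includes enumeration
    and Bayesian model reduction over the 63 combinations of six synaptic
    parameter groups, softmax model comparison, greedy pruning of redundant
    second-level effects, split-half intraclass-correlation reliability, and
    a synthetic-cohort generator so the full pipeline can be exercised
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
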