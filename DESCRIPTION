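Package: clathrid
Title: Structure-Resolved Reaction-Diffusion Modeling of Clathrin Coat
    Nucleation on Membranes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Stochastic, structure-resolved reaction-diffusion simulation and
    analysis of clathrin-coated structure nucleation on membranes. Rigid
    clathrin trimers and adaptor proteins bind through interface sites with
    Green's-function association probabilities, dimensional reduction of rates
    on the membrane, cooperative adaptor-enhanced bonds, and strained ring
    closure. Trajectories are summarized by lag/exponential growth fits,
    cluster-size free-energy landscapes with critical-nucleus intercepts, and
    first-passage times; phenomenological closed-form models predict lag time
    and growth steepness from microscopic parameters. A discrete Helfrich
    bending-energy minimizer couples a periodic triangulated membrane to rigid
    pre-assembled clathrin cages to report the bending cost per trimer.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    minpack.lm,
    jsonlite,
    generics
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
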