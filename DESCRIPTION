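Package: straincoex
Title: Multi-Strain SIS Co-Colonization Dynamics via the Replicator Equation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis of coexistence in endemic
    susceptible-infected-susceptible (SIS) systems where N closely related
    strains interact through altered susceptibilities to co-colonization.
    Provides the full N+N^2 compartment epidemiological model, its
    slow-timescale reduction to an N-dimensional replicator equation whose
    pairwise invasion fitnesses are tuned by the single-to-co-colonization
    ratio, exhaustive enumeration of steady states over strain supports with
    simplex-restricted stability analysis, and Monte-Carlo ensemble
    experiments over random interaction matrices that quantify pairwise
    outcome probabilities, diversity-stability relationships, multistability
    and strain-overlap patterns, and the analytic laws of the two extreme
    colonization regimes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
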