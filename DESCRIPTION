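Package: stereorecip
Title: Indirect Reciprocity with Stereotyped Reputations in Group-Structured
    Populations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Game-theoretic analysis of cooperation sustained by reputations
    when individuals can judge others either by individual reputations or by
    stereotypes assigned to whole groups. Solves mean-field equilibrium
    reputations under the four canonical second-order social norms and nine
    monitoring-scale combinations (private, group-wise, public), computes
    strategy fitness and cooperation rates, integrates replicator dynamics of
    competing strategies, analyzes adaptive dynamics of the stereotype-use
    propensity (invasion fitness, singular points, bifurcation sweeps,
    pairwise invasibility plots), and runs seed-reproducible finite-population
    stochastic simulations with Fermi pairwise-comparison imitation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
LinkingTo: Rcpp
Config/testthat/edition: 3
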