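Package: explora
Title: Explorability and Dynamical Robustness of Sparse Interaction Networks
Version: 0.1.0
Authors@R:
    person("Repo", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to study why interaction networks of living systems
    (ecological communities, gene-regulatory and metabolic networks) are
    sparse, i.e. have connectivity scaling as C = c1/S with system size S.
    Implements generalized Lotka-Volterra (GLV) fixed-point and linear
    stability analysis, tree-like ("tree with one loop") topology
    generators, the inverse problem recovering interaction weights from a
    target equilibrium, the explorability score V_E (volume of feasible and
    stable fixed points reachable by tuning interaction strengths), a
    dynamical-robustness statistic R based on the fifth percentile of the
    spectral abscissa under random perturbations of the dynamics, stochastic
    hill-climbing optimization of extra-link weights, inverse-scaling fits
    of connectivity against size, and a Monte-Carlo demonstration of the
    May instability criterion.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr
Config/testthat/edition: 3
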