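Package: nichepack
Title: Eco-Evolutionary Simulation of Niche Packing and Metastable Diversity
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates adaptive radiations under Lotka-Volterra competition on a
    two-dimensional continuous phenotype space with three complementary
    frameworks: quasi-deterministic adaptive dynamics (canonical-equation trait
    flow with stochastic branching, merging and extinction), a fully stochastic
    individual-based birth-death model, and a deterministic reaction-diffusion
    density formulation. Includes an analysis layer for species clustering,
    invasion-fitness landscapes, limit-cycle (Red Queen) detection and
    metastability probing, plus configuration, sweep and command-line
    orchestration utilities for studying alternative metastable levels of
    diversity.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
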