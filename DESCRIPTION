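Package: ffsdesorb
Title: Forward Flux Sampling of Polymer Desorption Kinetics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes desorption rates of single coarse-grained bead-spring
    polymer chains from an attractive flat wall using forward flux sampling
    (multilevel splitting) over overdamped Langevin dynamics. Provides the
    chain models (freely jointed and freely rotating chains, with optional
    excluded volume and a torsion-like 1-4 potential), a Steele 10-4-3 wall,
    a smooth contact-number reaction coordinate, adaptive interface
    placement with fixed-selection trial allocation, genealogy-aware
    intraclass-correlation error analysis, brute-force mean-first-passage
    reference estimators, a double-well validation harness, and the scaling
    analyses (mean-field strong-adsorption law, weak-adsorption power law,
    simulation-to-experiment time conversion).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
SystemRequirements: C++17
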