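Package: a2forest
Title: Predicting Sub-Monomer A2 Domain State of von Willebrand Factor
    Multimers in Shear Flow with Random Forests
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Coarse-grained Brownian-dynamics simulation of von Willebrand
    Factor (vWF) multimers in bulk shear flow, represented as bead-spring
    chains whose A2 domains are finitely extensible nonlinear elastic (FENE)
    springs, together with a machine-learning pipeline that predicts the
    instantaneous folded/unfolded state of the A2 domains from macromolecular
    conformational features.  The chain is partitioned along its contour at
    chain-level, 5-segment and 10-segment resolutions; per-partition
    conformational descriptors (radii of gyration, maximum spans, end-to-end
    distance, flow-variation fraction, local chain concentration, principal
    component projections, centre-of-mass velocities) plus raw bead positions
    feed per-segment random-forest classifiers.  Gini-impurity feature
    importances are aggregated to reveal the correlated segment dynamics that
    accompany A2 unfolding along the multimer contour.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    ranger,
    jsonlite,
    graphics,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    randomForest
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
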