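Package: immunofis
Title: Information-Theoretic Comparison of Immune Cell Composition Profiles
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Compares lymphocyte subset composition profiles between patient
    cohorts sampled longitudinally after hematopoietic cell transplantation.
    Implements an information-theoretic overlap index between composition
    profiles (normalized generalized Jensen-Shannon overlap), a case-versus-
    control-set distance, a random feature-subset Feature Importance Score
    (FIS) analysis with Wilcoxon signed-rank and false-discovery-rate
    significance calling, similarity-based hierarchical clustering with Newick
    export, distance trajectories over post-transplant visits, a Wilcoxon
    rank-sum comparison battery with reciprocal-of-comparisons significance
    cutoffs and significance-masked fold-change heatmaps, per-visit principal
    component convergence summaries, and a seeded Dirichlet-multinomial
    generator of three-cohort longitudinal immunophenotyping datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    ape,
    jsonlite,
    yaml,
    rlang,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
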