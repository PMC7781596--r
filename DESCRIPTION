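Package: flexgoal
Title: Population Analyses for a Multi-Start Multi-Goal Spatial Working-Memory Task
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Simulation and analysis battery for delay-period working-memory
    representations in prefrontal population recordings from a multi-start,
    multi-goal, multi-route (MSMGMR) spatial task. Provides a ground-truth
    synthetic session generator (balanced pseudorandom trial sequences,
    inhomogeneous-Poisson spike trains with configurable start/goal/egocentric/
    conjunctive/sequence selectivity, band-limited LFP, LED tracking),
    preprocessing filters for stable putative principal cells,
    population-vector correlation decoding, Kruskal-Wallis selectivity
    screening with FDR control, leave-one-out cross-validated population
    decoding with class balancing across four classifier families, LFP
    phase-of-firing analyses via the Hilbert transform, jitter-corrected
    spike cross-covariance and the cross-correlation selectivity index
    (CCSI), and t-SNE embedding of task-epoch population vectors.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    glmnet,
    e1071,
    ranger,
    Rtsne,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
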