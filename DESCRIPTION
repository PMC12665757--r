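Package: triagonist
Title: Multi-Task Graph Attention Modelling and Evolutionary Design of
    Triple-Agonist Peptides
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing peptide agonists of the three incretin-axis
    receptors GCGR, GLP1R and GIPR. Provides tokenization of peptide sequences
    with bracketed non-standard residues, ProtParam-compatible physicochemical
    profiling (molecular weight, isoelectric point, instability index, GRAVY,
    estimated logP and polar surface area), residue-graph construction, a
    multi-task GATv2 graph-attention classifier with Set2Set readout trained by
    a three-stage transfer-learning protocol, stratified cross-validation with
    masked multi-label metrics, a multi-objective genetic algorithm over token
    sequences (binding, motif preservation, biological plausibility, novelty
    and diversity objectives), and a synthetic sequence-activity data generator
    with a planted, recoverable structure-activity rule for offline validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
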