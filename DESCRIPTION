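Package: spotalign
Title: Mapping Single-Cell Transcriptomes to Spatial Transcriptomics Spots by Balanced Assignment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Aligns individual single-cell RNA-seq transcriptomes to spots of a
    spatial transcriptomics (ST) sample by solving a balanced linear assignment
    problem over replicated sub-spots with a shortest-augmenting-path
    (Jonker-Volgenant) solver that returns dual optimality certificates.
    Includes estimation of cells per spot from UMI content, harmonization of
    per-cell-type cell numbers by duplication or gene-wise generation,
    correlation- and distance-based cost matrices, naive per-cell baselines, a
    binned mode for single-cell-resolution ST, a simulation framework with
    ground truth (spatially structured synthetic tissues, within-type gene
    permutation, exponentiated-Gaussian expression noise, input-perturbation
    models), and evaluation utilities (mapping precision, marker discovery,
    SVM-based confidence scores, near/far spatial partitioning, fold-change
    ranked gene lists, retention index).
License: MIT
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    e1071,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
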