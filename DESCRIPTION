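Package: ligandmods
Title: Multi-Omic Module Detection and Phenotype Association for Ligand
    Perturbation Experiments
Version: 0.1.0
Authors@R: person("LINCS", "Tools", email = "tools@example.org", role = c("aut", "cre"))
Description: Simulates multi-ligand, multi-time-point, multi-assay perturbation
    experiments with planted ground truth and runs an integrative analysis
    pipeline on them: per-feature Gaussianizing scaling, control-relative
    differential signatures with Benjamini-Hochberg correction, PCA-based
    attribution of variance to experimental covariates, gap-statistic model
    selection with consensus partitioning-around-medoids module detection,
    single-cell spatial and cell-cycle phenotype metrics, lineage migration
    quantification, and linear module-phenotype association.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    glmnet,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
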