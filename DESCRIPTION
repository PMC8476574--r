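Package: spatialpheno
Title: Spatial Immunophenotyping of Tumors from Cell Maps and Gene Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies the spatial organization of CD8+ T cells in tumors and
    classifies samples into excluded, ignored and inflamed immunophenotypes.
    Computes cell densities per imaging stamp from multiplexed-immunofluorescence
    cell tables and assigns phenotypes by density thresholds at the tumor border
    and center; trains a nearest-centroid Spearman rank-correlation gene
    classifier of the phenotypes from labelled expression cohorts; evaluates
    classifiers and response biomarkers with multiclass confusion metrics,
    negative/positive predictive values, ROC/AUC and logistic odds ratios; and
    summarizes T cell receptor repertoire clonality with the Gini-Simpson index.
    Seeded simulators of expression cohorts, stamp-based cell point patterns and
    clonotype repertoires make every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
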