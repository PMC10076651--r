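Package: symptomnet
Title: Symptom Network Analysis of Burnout and Depression Questionnaires
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Regularized partial-correlation (Gaussian graphical model) network
    analysis for item-level questionnaire data, built around the workflow used
    in occupational mental-health comorbidity studies. Provides scoring and
    severity classification for the Maslach Burnout Inventory - General Survey
    (MBI-GS) and the Zung Self-Rating Depression Scale (SDS), nonparanormal
    marginal normalization, redundant-node screening, graphical lasso
    estimation with extended BIC model selection, expected influence / bridge
    expected influence / predictability centrality, Walktrap community
    detection, bootstrap accuracy and case-dropping stability (CS coefficient),
    and a permutation-based network comparison test. A synthetic-data module
    generates ordinal responses from a known sparse precision matrix with
    planted community and bridge structure for validation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    igraph,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    mclust,
    MASS
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
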