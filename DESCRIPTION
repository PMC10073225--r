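Package: braingut
Title: Brain-Gut Machine Learning Classification of Obesity from
    Structural Connectomes and Fecal Metabolomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discriminates obese from overweight individuals by combining
    nodal graph metrics of DTI-derived structural brain networks with fecal
    metabolite abundances. Implements volume-normalized connectome weighting
    and nodal network metrics (strength, betweenness centrality, eigenvector
    centrality, average path length), linear-SVM recursive feature
    elimination with a leave-one-out cross-validated optimal-subset-size
    search and ten-fold vote aggregation, final linear classifiers (SVM,
    ridge, logistic) evaluated by leave-one-out cross-validation, a combined
    brain-plus-metabolite model built by merging top-weighted features, and
    a label-permutation null. Includes a synthetic-cohort generator with
    planted group effects so the full pipeline is testable without subject
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    glmnet,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
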