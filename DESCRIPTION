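Package: clefthet
Title: Genetic Risk Prediction Allowing for Phenotypic Heterogeneity
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Likelihood-ratio ensemble risk prediction for diseases with
    heterogeneous sub-phenotypes, as arises for oral clefts. Provides
    nonparametric genotype-combination likelihood-ratio scoring, ROC-based
    forward SNP selection, data-driven agglomerative merging of
    sub-phenotypes into genetically homogeneous groups, K-fold
    cross-validated selection of the number of groups, and a case-control
    genotype simulator with known latent etiology groups for method
    validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
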