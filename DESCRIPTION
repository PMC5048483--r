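Package: mimfa
Title: Multiple Imputation Multiple Factor Analysis for Multi-Omics Data with Missing Rows
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrates several omics data tables measured on the same individuals
    when some individuals are missing entire rows in some tables. Missing rows are
    filled by stratified multiple hot-deck imputation, multiple factor analysis (MFA)
    is run on each completed dataset, and the resulting configurations are combined
    into a STATIS compromise with per-individual uncertainty regions (95% confidence
    ellipses and convex hulls). Includes mean-variable and regularized iterative
    imputation baselines, Procrustes alignment and RV-coefficient evaluation against
    a reference configuration, and a synthetic stratified multi-table data generator
    with configurable missing-row scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    jsonlite,
    vegan
Suggests:
    testthat (>= 3.0.0),
    cluster,
    optparse
Config/testthat/edition: 3
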