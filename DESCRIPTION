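Package: enrichdt
Title: Disease-Gene Classification from Network-Neighborhood Functional Enrichment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Encodes genes as vectors of -log10 hypergeometric enrichment
    p-values of their interaction-network neighborhoods against GO-like and
    pathway gene sets, filters the features with the Boruta shadow-feature
    algorithm, ranks them by max-relevance/min-redundancy (mRMR) mutual
    information, selects a feature count by incremental feature selection
    with a SMOTE-balanced CART decision tree under stratified 10-fold
    cross-validation, and extracts quantitative IF-THEN classification
    rules from the final tree. Includes a synthetic-data generator with
    planted neighborhood-enrichment signal so the whole pipeline is
    testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    ranger,
    rpart,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
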