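Package: mpathbench
Title: Benchmarking Metabolite Pathway Prediction from Atom-Color Substructure Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds and evaluates benchmark datasets for predicting the
    metabolic pathway involvement of metabolites from their molecular
    structure. Parses MDL V2000 molfiles into molecular graphs, generates
    canonical atom-color substructure count features at bond inclusivity
    0 to 3, assembles multi-label pathway datasets with duplicate merging
    and curation support, selects a non-hydrogen atom count threshold by
    sliding-window misclassification analysis, trains per-pathway binary
    classifiers (random forest, gradient boosted trees, multilayer
    perceptron with autoencoder compression) under repeated stratified
    cross-validation, and reports weighted performance aggregates,
    relative feature importance, and feature presence odds ratios. A
    synthetic molecular-graph generator with planted substructure motifs
    makes the full pipeline testable without any database download.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    ranger,
    xgboost,
    nnet
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
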