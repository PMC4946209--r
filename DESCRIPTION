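Package: trialdedup
Title: Duplicate Detection and Hidden-Duplicate Estimation for Clinical
    Trial Registries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to analyse duplicate registrations in multi-registry
    clinical-trial data of the kind aggregated by the WHO International
    Clinical Trials Registry Platform (ICTRP). Registry records are grouped
    into known duplicates by matching secondary identifiers to registry IDs,
    scored pairwise with a field-tagged, IDF-weighted binary cosine
    similarity via an exact (lossless) thresholded similarity join, and the
    number of previously unidentified ("hidden") duplicates is estimated by
    stratified sampling of high-similarity candidate pairs with exact
    Clopper-Pearson binomial confidence intervals. Includes a synthetic
    registry corpus generator with planted duplicate ground truth, and a
    rule engine encoding manual duplicate-adjudication criteria.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    Matrix,
    methods,
    Rcpp,
    stats,
    tibble,
    utils,
    xml2
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
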