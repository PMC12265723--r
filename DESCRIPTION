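Package: hdclassify
Title: Hyperdimensional Computing Classification for Microbial Abundance Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A brain-inspired hyperdimensional computing (HDC) classifier for
    high-dimensional quantitative microbial profiles. Relative abundances are
    quantized onto level hypervectors, samples are encoded by position-permuted
    bundling in a 10,000-dimensional bipolar space, and classes are represented
    as associative-memory hypervectors queried by cosine similarity, with an
    iterative retraining step that corrects misclassified training samples.
    Includes a backward-variable-elimination feature selection wrapper with
    per-feature importance scores, a stratified cross-validation and F1-based
    evaluation protocol with a four-way classifier comparison rule, adapters to
    classical baseline classifiers, readers and writers for abundance tables
    and study metadata with balance-score filtering, and a synthetic generator
    for sparse compositional abundance data with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    rpart,
    e1071,
    ranger,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
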