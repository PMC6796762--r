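Package: sixma
Title: Two-Layer Ensemble Prediction of DNA N6-Methyladenine Sites
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Predicts N6-methyladenine (6mA) sites in plant genomic DNA from
    41-nucleotide adenine-centered sequence windows. Five sequence encodings
    (a numerical nucleotide mapping, mononucleotide and dinucleotide binary
    codes with local position-specific dinucleotide frequencies,
    ring-function-hydrogen chemical properties with prefix densities, and
    nearest-neighbour similarity features) feed per-encoding support vector
    machine and extremely randomized tree models. Within each classifier the
    five probability streams are blended by a grid-searched weighted ensemble,
    and the two classifiers are averaged to give the final call. Includes
    F-score feature ranking with sequential forward search, stratified
    cross-validation with MCC and AUC reporting, McNemar tests for comparing
    predictors, and a synthetic-data generator so the whole pipeline can be
    exercised without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    e1071,
    ranger,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    xgboost
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
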