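Package: tcmdx
Title: Assistive Diagnosis for Traditional Chinese Medicine from Clinical Notes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: An offline pipeline for assistive diagnosis in traditional Chinese
    medicine (TCM) from freestyle electronic health record notes. Clinical named
    entities (symptoms, durations, tongue and pulse observations, history items)
    are extracted with a bidirectional recurrent encoder topped by a linear-chain
    conditional random field, assembled into structured records, and turned into
    time-weighted feature vectors. A text-convolution network predicts the TCM
    disease with ranked top-k output, and a per-disease integrated model --
    a majority-rule vote over a back-propagation network, a support vector
    classifier, a random forest and extreme gradient boosting -- predicts the
    syndrome. A seeded synthetic-corpus generator with gold annotations, quality
    control filtering, class rebalancing (downsampling and synthetic minority
    oversampling) and stratified partitioning make the whole system trainable
    and testable without access to hospital data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    yaml,
    stats,
    utils,
    nnet,
    e1071,
    randomForest,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
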