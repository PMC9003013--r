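Package: dynconn
Title: Static and Dynamic EEG Functional-Connectivity Brain Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds static and sliding-window dynamic functional-connectivity
    networks from multichannel EEG using magnitude-squared coherence, the
    imaginary part of coherency, the phase lag index, and Pearson correlation;
    thresholds them by a connectivity-preserving edge-removal rule; extracts
    graph-theoretic features (small-world index, vertex strength, path length,
    transitivity, diameter) and their sliding-window summaries; and evaluates
    two-group discrimination with six classifier families under leave-one-out
    cross-validation. Includes a synthetic two-group EEG cohort generator with
    controllable inter-channel phase coupling, an EDF and delimited-text
    reader/writer, and an end-to-end experiment pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    signal,
    pROC,
    e1071,
    rpart,
    randomForest,
    nnet,
    withr,
    stats,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
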