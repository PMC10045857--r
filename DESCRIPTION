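Package: elmeeg
Title: Extreme Learning Machines for Epileptic Seizure Recognition from EEG Chunks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Seizure versus non-seizure classification of one-second EEG chunks
    with a single-hidden-layer Extreme Learning Machine (ELM): a frozen random
    sigmoid hidden layer whose output weights are solved analytically as the
    minimum-norm least-squares solution via the Moore-Penrose pseudoinverse.
    Includes a reader/writer for the tabular 178-sample EEG chunk dialect,
    label binarization and unit-variance rescaling, stratified train/
    validation/test splitting, a connection-weight feature-selection algorithm
    that ranks input channels by aggregated input-to-hidden and hidden-to-
    output weight products, a full evaluation harness (confusion matrix,
    accuracy, precision, recall, F1, specificity, sensitivity, ROC/AUC with a
    rank-based cross-check), a synthetic five-class EEG chunk generator for
    end-to-end testing without external downloads, and an experiment runner
    covering the canonical 80/20, 70/30 and 60/40 protocols with optional
    off-the-shelf baselines.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    MASS,
    pROC,
    e1071,
    rpart,
    randomForest,
    nnet,
    class,
    jsonlite,
    optparse
Config/testthat/edition: 3
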