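Package: hierovr
Title: Hierarchical One-vs-Rest Biomarker Discovery from Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Grade-specific biomarker discovery from bulk expression (TPM)
    matrices via a greedy hierarchical one-vs-rest classification scheme.
    Each internal node of the hierarchy isolates one class from the rest
    using class-imbalance correction (SMOTE oversampling plus the
    neighbourhood cleaning rule), hybrid feature selection (an
    information-gain filter followed by a minimum-redundancy
    maximum-relevance wrapper driven by linear-SVM cross-validated
    accuracy), and a per-node choice between Gaussian naive Bayes and
    linear SVM classifiers. Ships a synthetic TPM-matrix generator with
    planted class-specific markers so the whole pipeline is testable
    without external data, a full metric suite (accuracy, sensitivity,
    specificity, F-measure, Matthews correlation, ROC area), JSON model
    serialization, and command-line entry points.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    e1071,
    jsonlite,
    pROC,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
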