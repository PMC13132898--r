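Package: eegfatigue
Title: Limited-Channel EEG Fatigue Detection and Channel Screening
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Subject-independent detection of physical and mental fatigue from
    wearable four-channel EEG (TP9, AF7, AF8, TP10 at 256 Hz). Segments
    recordings into fixed 10-second windows per task event, extracts a
    16-feature battery (statistical moments, seven entropy measures, band
    powers and spectral entropy), labels fatigue from subjective scores by
    threshold, trains classifiers under leave-one-subject-out cross-validation
    with minority-class oversampling confined to training folds, and ranks all
    channel combinations by a cost-weighted Score that prioritises fatigue
    recall over specificity. Includes a synthetic cohort generator emulating
    the session/event structure of graded treadmill plus task-switching
    protocols so the whole pipeline is testable without recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    glmnet,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
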