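Package: readeracc
Title: Diagnostic Accuracy of Paired Readers Against a Reference Standard
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Evaluates binary diagnostic calls made by two readers (for
    example a reporting radiologist and an image-analysis algorithm) against a
    shared reference standard such as a contemporaneous CT report. Provides
    per-finding sensitivity and specificity with exact Clopper-Pearson
    intervals, Cohen's kappa with analytic or bootstrap intervals, a paired
    case-resampling bootstrap for the difference in kappa between readers, an
    OR-rule hybrid reader, ROC/AUC for score-producing readers, and a
    synthetic generator of paired-reader cohorts with controllable
    inter-reader dependence so the whole pipeline is testable without
    patient data. Ships the confusion counts of a published trauma chest
    radiograph reader study as a worked fixture.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    readr,
    stats,
    tibble,
    utils,
    withr
Suggests:
    e1071,
    jsonlite,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
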