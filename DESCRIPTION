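Package: rnflasym
Title: Inter-Eye RNFL Thickness Asymmetry Metrics for Glaucoma Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes inter-eye asymmetry metrics of peripapillary retinal
    nerve fiber layer (RNFL) thickness from paired optical coherence
    tomography (OCT) sector measurements, characterizes their group
    statistics (half-normal behaviour of absolute differences, rank-sum
    group comparison, notched box-plot summaries), trains interpretable
    class-weighted binary classification trees with a split budget and
    stratified cross-validated misclassification loss, and evaluates
    screening performance (accuracy, sensitivity, specificity, precision)
    from confusion matrices. Includes a calibrated synthetic paired-eye
    cohort generator so the full pipeline can be exercised without patient
    data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    rpart,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
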