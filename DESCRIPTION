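Package: outlierscreen
Title: Outlier Screening of Clinical Cohorts for Candidate Discovery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An augmented-intelligence screening pipeline for tabular clinical
    cohorts. Flags point outliers with an isolation forest (anomaly-score
    z-thresholding) and contextual outliers as observations a random-forest
    outcome classifier mislabels with a tree-vote confidence above 0.90, after
    variable filtering, structured "not applicable" fills, and ten-round
    iterative regression imputation. Produces reviewer-facing characterization
    tables with small-cell suppression and structured case narratives, and
    ships a synthetic pregnancy-cohort generator with planted ground-truth
    outliers so every stage is testable without patient data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    nnet,
    ranger,
    stats,
    tools,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
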