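Package: actipatterns
Title: Diel Physical-Activity Pattern Clustering from Minute-Level Accelerometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for clustering participants by their within-day
    physical-activity patterns from minute-level accelerometer MET traces:
    wear-time validity filtering (7 days at >= 8 h/day), missing-minute
    imputation, two feature constructions (raw 10,080-minute MET vectors and
    unit-normalized 1440-minute MVPA-frequency profiles), Lloyd k-means with
    random restarts and elbow-based selection of the number of clusters,
    MVPA bout quantification under 1-, 5- and 10-minute criteria,
    loess-smoothed diel activity curves, and chi-square/ANOVA comparison of
    covariates across clusters. Includes a synthetic-cohort generator with
    planted temporal archetypes so the whole pipeline is testable without
    trial data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
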