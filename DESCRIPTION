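Package: pnaqsar
Title: Multitask QSAR for Receptor Tyrosine Kinases with Principal
    Neighborhood Aggregation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A multitask quantitative structure-activity relationship
    (QSAR) modelling toolkit for predicting pIC50 against seven receptor
    tyrosine kinases (ALK, EGFR, ERBB2, ERBB4, MET, RET, ROS1). Couples a
    principal-neighborhood-aggregation (PNA) graph neural network on
    molecular graphs with a deep network on PCA-reduced concatenated
    fingerprints, trained with a masked multitask loss and early stopping.
    Includes the full supporting pipeline: activity-record curation
    (deduplication, IQR outlier removal, cross-source merging),
    activity-cliff generator removal, task labelling and stratified
    splitting, stratified 10-fold cross-validation with Golbraikh-Tropsha
    acceptability criteria, a two-stage Tanimoto/ECFP4 applicability
    domain, a synthetic-library generator for offline testing, and a
    command-line screening interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    igraph,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
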