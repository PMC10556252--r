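Package: gapeforce
Title: Neural Encoding and Population Decoding of Bite Force and Gape
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for single-neuron and population-level encoding
    of bite force and static gape in orofacial sensorimotor cortex during an
    incisor biting task with nine trial types (3 gapes x 3 force levels).
    Provides point-process Bernoulli generalized linear models of 4-ms spike
    trains with raised-cosine spike-history filters and multi-lag bite-force
    covariates, cross-validated AUROC model comparison, demixed principal
    components analysis of trial-averaged population activity, time-resolved
    single-trial classification with shuffle-based significance, and a
    synthetic-data generator with known ground truth for parameter-recovery
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    grDevices,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
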