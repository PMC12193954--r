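Package: pdposts
Title: Mining Longitudinal Facebook Archives for Parkinson's Disease-Related Posting
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying Parkinson's disease (PD)-related content in
    participant-donated Facebook data exports. The package harvests author text
    from multi-file JSON archives, repairs text encoding, strips shared-memory
    timestamps, removes exact and near duplicates (180-second rule), flags
    candidate posts with a PD term dictionary, classifies dictionary-flagged
    posts with a recall-optimized model selected among seven classifier
    families, augments the classifier with explicit-mention rules, and compares
    the percentage of PD-related posts before and after diagnosis with a
    nonparametric statistical battery. A synthetic-cohort generator with known
    ground-truth labels makes every stage testable without access to real
    participant data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    digest,
    e1071,
    graphics,
    jsonlite,
    methods,
    ranger,
    rpart,
    stats,
    stringi,
    utils,
    xgboost,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
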