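Package: mutriage
Title: Missense Mutation Triage by Composite Evidence Scoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Triage pipeline for ranking missense mutations in multidomain
    proteins. Parses COSMIC-style mutation catalogs, validates them against a
    reference sequence, annotates each substitution with normalized evidence
    features (substitution-matrix penalties, evolutionary conservation,
    external pathogenicity probability, structural location, polarity change,
    binding-site proximity), combines the features into a weighted composite
    score with least-squares weight calibration, and ranks and selects
    candidate mutations. Ships the talin-1 reference case as a bundled
    fixture and a synthetic-study generator for end-to-end testing without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    IRanges,
    MASS,
    readr,
    rlang,
    S4Vectors,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
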