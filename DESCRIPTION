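Package: epilinkr
Title: Privacy-Preserving Record Linkage and Secure Intersection
    Cardinality with Bloom-Filter EpiLink Similarity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Fault-tolerant (fuzzy) record linkage between two patient
    databases using the EpiLink weighted similarity over Bloom-filter
    encoded identifying fields, with exchange groups and two-threshold
    match classification.  The same linkage circuit is evaluated
    obliviously under full-threshold secret sharing (Boolean GMW-style
    XOR sharing and additive arithmetic sharing with Beaver-triple
    multiplication), revealing only the number of common patients
    between the two databases.  Includes a synthetic patient-data
    generator with a controlled three-dataset overlap design and a
    configurable corruption model, so every stage is testable end to
    end without access to real patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    openssl,
    purrr,
    readr,
    rlang,
    stats,
    stringi,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
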