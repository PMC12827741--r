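Package: pseudolink
Title: Pseudonymization, Error-Tolerant Record Linkage, and Consent
    Management for Patient Registries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained toolkit for managing patient identities in
    medical research networks: generation and verification of
    error-detecting/correcting alphanumeric patient identifiers,
    deterministic derived pseudonyms (CryptoID, vocabulary-based
    ElasticID), hybrid transport encryption of pseudonyms,
    error-tolerant probabilistic record linkage with a weighted
    two-threshold classifier, privacy-preserving linkage on Bloom-filter
    encodings, Soundex and locality-sensitive-hashing blocking, modular
    informed-consent management with FHIR-style serialization, a
    session/token delegation model with multi-tenant role-based access
    control and an audit trail, plus CSV batch import/export and a
    synthetic-cohort generator with ground-truth duplicates for
    evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    openssl,
    readr,
    rlang,
    stringi,
    tibble,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
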