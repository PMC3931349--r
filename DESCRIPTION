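Package: dronr
Title: Build a Modular Drug Ontology from Historical RxNorm-Format Releases
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An extract-transform-load pipeline that turns a chronological
    series of RxNorm Rich Release Format (RRF) releases into a modular OWL 2
    drug ontology. It tracks drug-concept identifier (RXCUI) provenance across
    retirements, merges and splits via a transitively closed deprecation table,
    accumulates a comprehensive historical National Drug Code (NDC) registry,
    maps ingredients to ChEBI classes by exact lexical matching over labels and
    synonyms, mines disposition-ingredient links from ChEBI roles, normalizes
    everything into an entity graph of ingredients, dispositions, clinical drug
    forms, clinical drugs, branded drugs and packaged drug products, and emits
    five OWL 2 modules (dron-full, dron-chebi, dron-rxnorm, dron-pro,
    dron-upper) in deterministic RDF/XML. A seeded synthetic-fixture generator
    produces RRF release series and mini-ChEBI snapshots with a ground-truth
    manifest so the whole pipeline is testable without licensed UMLS data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    stringr,
    rlang,
    xml2,
    ggplot2,
    generics,
    jsonlite,
    withr,
    utils,
    stats
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
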