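Package: pgdbwatch
Title: Release-to-Release Update Notifications for Pathway/Genome Databases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Compares two releases of a curated pathway/genome database
    (attribute-value flatfiles in the style of Pathway Tools .dat exports),
    expands user subscriptions for genes, pathways, Gene Ontology terms and
    pathway classes into their interest closures of functionally related
    objects, decides which subscriptions warrant notification under a
    new-citation significance criterion, and renders one concise, linked
    change digest per user per database. Includes a seeded synthetic-fixture
    generator with ground-truth edit scripts and an independent brute-force
    oracle for validating the notification pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
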