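Package: phifair
Title: FAIR Publishing Toolkit for Pathogen-Host Interaction Records
Version: 0.1.0
Authors@R:
    person("phifair", "developers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Transforms pathogen-host interaction records from a bespoke
    XML dump into a FAIR (Findable, Accessible, Interoperable, Reusable)
    Linked Data resource. Parses and filters interaction records,
    harmonizes free-text descriptive fields to controlled-vocabulary URIs
    via curated identity-mapping tables, builds an SIO-style RDF model
    (interactions, contexts, alleles, genes, typed Identifiers.org
    cross-references) with opaque minted URIs, and publishes the result
    through a two-layer repository/record metadata accessor plus a dual
    human/machine URI resolver. Includes a restricted SPARQL engine for
    the packaged exploration queries and a seeded synthetic-fixture
    generator so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    xml2,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
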