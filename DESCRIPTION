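Package: ontoforge
Title: Batch Generation of Ontology Classes from Design Patterns and Spreadsheets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Expands ontology design patterns into OWL axioms. Given a
    reusable axiom-settings file holding Manchester-syntax class-expression
    and annotation templates with spreadsheet-column variables, plus a
    populated data table (TSV, CSV or XLSX) with one term per row, ontoforge
    either mints new ontology classes (zero-padded OBO-style identifiers,
    with collision avoidance against an optional target ontology) or attaches
    new axioms to existing classes. Output is written as RDF/XML or Turtle,
    with the intermediate Manchester-syntax document exposed for debugging.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    xml2,
    utils,
    stats
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
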