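Package: metabind
Title: Metadata-Driven Integration of Heterogeneous Biological Data Sources
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Adaptive middleware for integrating previously unknown biological
    data sources at runtime without per-source wrapper code. A typed metadata
    registry (a generic API ontology) classifies data sources, their data
    elements, user operations, and the mapping from generic operations to
    concrete source calls. Generic wrappers parse structured flat files
    (GenBank record style) via declarative text schemas, extract values from
    XML documents via DTD-derived paths, drive web form submissions and scrape
    responses via indexed tag paths, and construct parameterized SQL against
    relational schemas. Complex user operations are orchestrated by XML state
    machines with Event-Condition-Action transition rules; each generic action
    is bound to a concrete callable at runtime by introspection over a typed
    execution context.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    xml2
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
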