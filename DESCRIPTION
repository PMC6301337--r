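Package: crucible
Title: Declarative, Message-Driven ETL for Scientific Metadata
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A horizontally composable extract-transform-load toolkit for
    scientific metadata. Source records in XML, CSV or JSON are converted to
    an ordered hierarchical document model, harvested through a declarative
    ingestion language compiled to lazy streaming cursors (with partitioning
    and parameterized inner joins), aligned to a target schema with the JSONTL
    transformation language (a JSONPath-subset matcher, five statement types,
    conditional expressions and sandboxed apply blocks), orchestrated through
    a status-routed message pipeline with at-least-once delivery, and exported
    as JSON lines, search-engine bulk actions or per-document files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    xml2,
    yaml,
    digest,
    R6,
    lubridate,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
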