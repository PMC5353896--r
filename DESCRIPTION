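Package: sparqlfed
Title: Federated SPARQL Query Processing over Life-Science Linked Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A federated SPARQL query engine for collections of life-science
    RDF endpoints. Builds a VoID-based catalogue of dataset summaries (classes,
    predicates, example resources, URI patterns, endpoint mirrors), performs
    hybrid triple-pattern-wise source selection (catalogue lookup followed by
    SPARQL ASK pruning) with full accounting of sources selected and ASK
    requests issued, rewrites SPARQL 1.0 queries into SPARQL 1.1 using
    exclusive groups as SERVICE blocks with UNION over shared patterns, and
    executes the rewritten query with per-service provenance instrumentation
    and endpoint availability monitoring. Ships a seeded generator of synthetic
    multi-endpoint federations in the style of the public life-science linked
    open data cloud for fully offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    tibble,
    tidyr,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
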