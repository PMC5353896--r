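# Vocabulary constants used across modules (file collates first).

NS_RDF <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#"
NS_RDFS <- "http://www.w3.org/2000/01/rdf-schema#"
NS_VOID <- "http://rdfs.org/ns/void#"
NS_DCT <- "http://purl.org/dc/terms/"
NS_XSD <- "http://www.w3.org/2001/XMLSchema#"
SFED_NS <- "http://purl.org/net/sparqlfed#"

#' Common vocabulary terms
#'
#' Encoded IRIs for `rdf:type` and `rdfs:label`, the two predicates present
#' in essentially every published dataset (and therefore in every synthetic
#' federation member).
#'
#' @format Encoded IRI strings (see [rdf_iri()]).
#' @export
RDF_TYPE <- paste0("<", NS_RDF, "type>")

#' @rdname RDF_TYPE
#' @export
RDFS_LABEL <- paste0("<", NS_RDFS, "label>")
RDF_VALUE <- paste0("<", NS_RDF, "value>")
SFED_PARTIAL <- paste0("<", SFED_NS, "partial>")

XSD_NUMERIC <- paste0(NS_XSD, c(
  "integer", "decimal", "double", "float", "int", "long", "short", "byte",
  "nonNegativeInteger", "positiveInteger", "negativeInteger",
  "nonPositiveInteger", "unsignedInt", "unsignedLong"
))
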