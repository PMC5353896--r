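#' RDF terms
#'
#' Terms are carried throughout the package in a compact N-Triples-style
#' string encoding, so that a triple table is an ordinary character tibble
#' and joins between solution tables are plain string joins:
#'
#' * IRIs as `<http://...>`
#' * literals as `"lexical"`, `"lexical"@en` or `"lexical"^^<datatype>`
#' * variables as `?name`
#' * blank nodes as `_:label`
#'
#' `rdf_iri()`, `rdf_literal()`, `rdf_var()` and `rdf_blank()` build encoded
#' terms; `term_kind()` classifies an encoded term and `term_is_bound()`
#' implements the usual boundness test (IRIs and literals are bound,
#' variables and blank nodes are not).
#'
#' @param iri,name,label Bare IRI string / variable name (no leading `?`) /
#'   blank node label.
#' @param x Lexical form of a literal, or a vector of encoded terms for the
#'   inspection helpers.
#' @param datatype Optional datatype IRI (bare, without angle brackets).
#' @param lang Optional language tag.
#' @return Encoded term string(s); `term_kind()` returns one of
#'   `"iri"`, `"literal"`, `"variable"`, `"blank"` per element.
#' @examples
#' rdf_iri("http://example.org/x")
#' rdf_literal("4.5", datatype = "http://www.w3.org/2001/XMLSchema#decimal")
#' term_kind(c("?x", "<http://a>", "\"lit\""))
#' @name rdf-terms
NULL

#' @rdname rdf-terms
#' @export
rdf_iri <- function(iri) {
  stopifnot(is.character(iri))
  paste0("<", iri, ">")
}

#' @rdname rdf-terms
#' @export
rdf_literal <- function(x, datatype = NULL, lang = NULL) {
  esc <- gsub("\n", "\\\\n", gsub("\"", "\\\\\"", gsub("\\\\", "\\\\\\\\", x)))
  out <- paste0("\"", esc, "\"")
  if (!is.null(lang)) {
    out <- paste0(out, "@", lang)
  } else if (!is.null(datatype)) {
    out <- paste0(out, "^^<", datatype, ">")
  }
  out
}

#' @rdname rdf-terms
#' @export
rdf_var <- function(name) paste0("?", sub("^[?$]", "", name))

#' @rdname rdf-terms
#' @export
rdf_blank <- function(label) paste0("_:", label)

#' @rdname rdf-terms
#' @export
term_kind <- function(x) {
  dplyr::case_when(
    startsWith(x, "<") ~ "iri",
    startsWith(x, "\"") ~ "literal",
    startsWith(x, "?") ~ "variable",
    startsWith(x, "_:") ~ "blank",
    TRUE ~ NA_character_
  )
}

#' @rdname rdf-terms
#' @export
term_is_bound <- function(x) term_kind(x) %in% c("iri", "literal")

#' @rdname rdf-terms
#' @export
#' @details `iri_value()` strips the angle brackets from an encoded IRI.
iri_value <- function(x) substr(x, 2L, nchar(x) - 1L)

is_var_term <- function(x) startsWith(x, "?")
# blank nodes in query patterns behave as non-projectable variables
is_varlike_term <- function(x) startsWith(x, "?") | startsWith(x, "_:")

# variable binding column name for a varlike term: "?x" -> "x", "_:b" -> ".b"
var_name <- function(x) {
  out <- character(length(x))
  qv <- startsWith(x, "?")
  out[qv] <- substring(x[qv], 2L)
  out[!qv] <- paste0(".", substring(x[!qv], 3L))
  out
}

#' Decompose an encoded literal
#'
#' @param x A single encoded literal term.
#' @return List with `lexical`, `datatype` (NA if plain), `lang` (NA if none).
#' @keywords internal
literal_parts <- function(x) {
  m <- regmatches(x, regexec('^"((?:[^"\\\\]|\\\\.)*)"(?:@([A-Za-z][A-Za-z0-9-]*)|\\^\\^<([^>]*)>)?$', x))[[1]]
  if (length(m) == 0) stop("not a literal term: ", x)
  lex <- m[2]
  lex <- gsub("\\\\n", "\n", lex)
  lex <- gsub('\\\\"', '"', lex)
  lex <- gsub("\\\\\\\\", "\\\\", lex)
  list(
    lexical = lex,
    lang = if (nzchar(m[3])) m[3] else NA_character_,
    datatype = if (nzchar(m[4])) m[4] else NA_character_
  )
}

#' Human label for an IRI
#'
#' Extracts the substring after the last of `#`, `:` or `/` (ignoring the
#' scheme's `://`), the convention used when cataloguing endpoints whose
#' vocabularies carry no rdfs:label.
#'
#' @param iri Encoded IRI term or bare IRI string.
#' @return Character label (possibly empty when the IRI ends in a delimiter).
#' @export
#' @examples
#' iri_local_name("http://bio2rdf.org/ns/kegg#Enzyme")
iri_local_name <- function(iri) {
  bare <- ifelse(startsWith(iri, "<"), substr(iri, 2L, nchar(iri) - 1L), iri)
  rest <- sub("^[A-Za-z][A-Za-z0-9+.-]*://", "", bare)
  vapply(rest, function(r) {
    pos <- gregexpr("[#:/]", r)[[1]]
    if (pos[1] == -1) r else substring(r, max(pos) + 1L)
  }, character(1), USE.NAMES = FALSE)
}
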