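#' Serialize a parsed query back to SPARQL text
#'
#' Emits standards-conformant SPARQL 1.1. The original query's prefix
#' declarations are re-emitted verbatim and used to compact IRIs; variables
#' are never renamed. Parsing the output yields an algebra equivalent to the
#' input (same BGP decomposition, patterns, filters and modifiers).
#'
#' @param q A `sparql_query` or `rewritten_query`.
#' @return A single SPARQL string.
#' @export
serialize_query <- function(q) {
  if (inherits(q, "rewritten_query")) return(q$text)
  stopifnot(inherits(q, "sparql_query"))
  px <- q$prefixes
  header <- if (length(px)) paste0("PREFIX ", names(px), ": <", px, ">") else character(0)
  proj <- if (identical(q$projection, "*")) "*" else paste0("?", q$projection, collapse = " ")
  first <- if (q$form == "SELECT") {
    paste0("SELECT ", if (q$distinct) "DISTINCT " else "", proj, " WHERE {")
  } else "ASK {"
  body <- serialize_node(q$algebra, px, indent = 1L)
  tail <- "}"
  mods <- character(0)
  if (nrow(q$order_by) > 0) {
    keys <- ifelse(q$order_by$desc, paste0("DESC(?", q$order_by$var, ")"),
                   paste0("?", q$order_by$var))
    mods <- c(mods, paste("ORDER BY", paste(keys, collapse = " ")))
  }
  if (!is.na(q$limit)) mods <- c(mods, paste("LIMIT", q$limit))
  if (!is.na(q$offset)) mods <- c(mods, paste("OFFSET", q$offset))
  paste(c(header, first, body, tail, mods), collapse = "\n")
}

serialize_term <- function(x, prefixes) {
  if (length(prefixes)) compact_iri(x, prefixes) else x
}

serialize_node <- function(node, prefixes, indent = 0L) {
  pad <- strrep("  ", indent)
  switch(node$type,
    unit = character(0),
    bgp = paste0(pad,
      serialize_term(node$patterns$s, prefixes), " ",
      serialize_term(node$patterns$p, prefixes), " ",
      serialize_term(node$patterns$o, prefixes), " ."),
    join = unlist(lapply(node$parts, function(p) {
      if (p$type == "union") {
        c(paste0(pad, "{"), serialize_node(p, prefixes, indent + 1L), paste0(pad, "}"))
      } else {
        serialize_node(p, prefixes, indent)
      }
    })),
    union = {
      blocks <- lapply(node$parts, function(p) {
        c(paste0(pad, "{"), serialize_node(p, prefixes, indent + 1L), paste0(pad, "}"))
      })
      out <- blocks[[1]]
      for (b in blocks[-1]) out <- c(out, paste0(pad, "UNION"), b)
      out
    },
    optional = c(
      serialize_node(node$left, prefixes, indent),
      paste0(pad, "OPTIONAL {"),
      serialize_node(node$right, prefixes, indent + 1L),
      paste0(pad, "}")
    ),
    filter = c(
      serialize_node(node$inner, prefixes, indent),
      paste0(pad, "FILTER (", serialize_expr(node$expr, prefixes), ")")
    ),
    service = c(
      paste0(pad, "SERVICE ", if (node$silent) "SILENT " else "",
             serialize_term(node$endpoint, prefixes), " {"),
      serialize_node(node$inner, prefixes, indent + 1L),
      paste0(pad, "}")
    ),
    stop("cannot serialize node of type ", node$type)
  )
}

serialize_expr <- function(expr, prefixes) {
  switch(expr$type,
    term = {
      t <- expr$term
      # plain xsd numerics and booleans read back naturally in short form
      if (term_kind(t) == "literal") {
        parts <- literal_parts(t)
        if (!is.na(parts$datatype) &&
            parts$datatype %in% c(paste0(NS_XSD, "integer"), paste0(NS_XSD, "decimal"),
                                  paste0(NS_XSD, "boolean"))) {
          return(parts$lexical)
        }
      }
      serialize_term(t, prefixes)
    },
    op = {
      if (expr$op == "!") {
        paste0("!(", serialize_expr(expr$args[[1]], prefixes), ")")
      } else {
        paste0("(", serialize_expr(expr$args[[1]], prefixes), " ", expr$op, " ",
               serialize_expr(expr$args[[2]], prefixes), ")")
      }
    },
    call = paste0(toupper(expr$fn), "(",
                  paste(vapply(expr$args, serialize_expr, character(1), prefixes),
                        collapse = ", "), ")"),
    stop("cannot serialize expression node of type ", expr$type)
  )
}
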