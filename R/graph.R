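#' In-memory RDF graphs
#'
#' A graph is a tibble with character columns `s`, `p`, `o` holding encoded
#' terms (see [rdf_iri()]). `rdf_graph()` builds one from vectors and drops
#' duplicate triples (RDF graphs are sets); `match_pattern()` evaluates a
#' single triple pattern against a graph, returning one solution row per
#' matching triple; `graph_ask()` is the boolean ASK form of the same.
#'
#' @param s,p,o Encoded subject/predicate/object term vectors (recycled).
#' @return `rdf_graph()` returns a tibble of distinct triples.
#' @export
#' @examples
#' g <- rdf_graph(rdf_iri("http://x/a"), RDF_TYPE, rdf_iri("http://x/C"))
#' match_pattern(g, "?s", RDF_TYPE, "?c")
rdf_graph <- function(s = character(), p = character(), o = character()) {
  dplyr::distinct(tibble::tibble(s = s, p = p, o = o))
}

#' @rdname rdf_graph
#' @param graph A triple tibble.
#' @export
match_pattern <- function(graph, s, p, o) {
  pos <- c(s = s, p = p, o = o)
  df <- graph
  for (nm in names(pos)) {
    if (!is_varlike_term(pos[[nm]])) df <- df[df[[nm]] == pos[[nm]], , drop = FALSE]
  }
  varpos <- pos[is_varlike_term(pos)]
  if (length(varpos) == 0) {
    return(tibble::as_tibble(df[, 0])[seq_len(nrow(df)), , drop = FALSE])
  }
  vn <- var_name(varpos)
  # same variable in several positions forces equality of those positions
  for (v in unique(vn)) {
    cols <- names(varpos)[vn == v]
    if (length(cols) > 1) {
      keep <- rep(TRUE, nrow(df))
      for (k in seq_along(cols)[-1]) keep <- keep & df[[cols[1]]] == df[[cols[k]]]
      df <- df[keep, , drop = FALSE]
    }
  }
  first <- !duplicated(vn)
  out <- df[, names(varpos)[first], drop = FALSE]
  names(out) <- vn[first]
  tibble::as_tibble(out)
}

#' @rdname rdf_graph
#' @export
graph_ask <- function(graph, s, p, o) {
  nrow(match_pattern(graph, s, p, o)) > 0
}

#' Merge the graphs of a federation into one
#'
#' Union of the per-dataset triple sets (duplicate triples across datasets
#' collapse, as they would in a single central store). Used as the
#' completeness oracle for federated execution.
#'
#' @param graphs A list of triple tibbles.
#' @return A single triple tibble.
#' @export
merge_graphs <- function(graphs) {
  dplyr::distinct(dplyr::bind_rows(graphs))
}

# --- serialization ----------------------------------------------------------

#' Read and write graphs as N-Triples or Turtle
#'
#' The encoded-term representation already is N-Triples syntax, so writing is
#' line-per-triple; `format = "turtle"` additionally emits `@prefix`
#' declarations and compacts IRIs. Reading accepts the Turtle subset produced
#' here and by [write_catalogue()] (prefixes, `a`, `;`/`,` lists and `[...]`
#' blank-node property lists).
#'
#' @param graph Triple tibble.
#' @param path File path.
#' @param format `"ntriples"` or `"turtle"` (writing; reading autodetects by
#'   content).
#' @param prefixes Named character vector (name -> namespace IRI) used to
#'   compact IRIs when writing Turtle.
#' @return `read_graph()` returns a triple tibble; `write_graph()` its `path`,
#'   invisibly.
#' @export
write_graph <- function(graph, path, format = c("ntriples", "turtle"), prefixes = NULL) {
  format <- match.arg(format)
  graph <- dplyr::arrange(graph, s, p, o)
  if (format == "ntriples") {
    lines <- paste(graph$s, graph$p, graph$o, ".")
  } else {
    if (is.null(prefixes)) prefixes <- c(rdf = NS_RDF, rdfs = NS_RDFS)
    shorten <- function(x) compact_iri(x, prefixes)
    lines <- c(
      paste0("@prefix ", names(prefixes), ": <", prefixes, "> ."),
      "",
      paste(shorten(graph$s), shorten(graph$p), shorten(graph$o), ".")
    )
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_graph
#' @export
read_graph <- function(path) {
  statements_to_graph(parse_turtle(readLines(path, warn = FALSE)))
}

statements_to_graph <- function(statements) {
  if (nrow(statements) == 0) return(rdf_graph())
  dplyr::distinct(tibble::as_tibble(statements[, c("s", "p", "o")]))
}

compact_iri <- function(x, prefixes) {
  out <- x
  iri <- startsWith(x, "<")
  bare <- substr(x[iri], 2L, nchar(x[iri]) - 1L)
  res <- bare
  done <- rep(FALSE, length(bare))
  for (pfx in names(prefixes)) {
    ns <- prefixes[[pfx]]
    hit <- !done & startsWith(bare, ns)
    local <- substring(bare[hit], nchar(ns) + 1L)
    ok <- grepl("^(?:[A-Za-z0-9_%-]|\\.(?=[A-Za-z0-9_%-]))*$", local, perl = TRUE) & !grepl("/", local)
    idx <- which(hit)[ok]
    res[idx] <- paste0(pfx, ":", substring(bare[idx], nchar(ns) + 1L))
    done[idx] <- TRUE
  }
  out[iri] <- ifelse(done, res, x[iri])
  out
}

# Convert a token (plus prefix map) to an encoded term.
token_to_term <- function(tk, prefixes, bnode_env = NULL) {
  switch(tk$type,
    IRIREF = tk$value,
    VAR = paste0("?", substring(tk$value, 2L)),
    BLANK = tk$value,
    NUMBER = {
      dt <- if (grepl("[.eE]", tk$value)) paste0(NS_XSD, "decimal") else paste0(NS_XSD, "integer")
      paste0("\"", tk$value, "\"^^<", dt, ">")
    },
    STRING = {
      m <- regmatches(tk$value, regexec('^("(?:[^"\\\\]|\\\\.)*")(?:@([A-Za-z][A-Za-z0-9-]*))?(?:\\^\\^(.+))?$', tk$value))[[1]]
      base <- m[2]
      if (nzchar(m[3])) {
        paste0(base, "@", m[3])
      } else if (nzchar(m[4])) {
        dt <- m[4]
        if (!startsWith(dt, "<")) dt <- expand_pname(dt, prefixes)
        paste0(base, "^^", dt)
      } else base
    },
    PNAME = expand_pname(tk$value, prefixes),
    NAME = {
      if (tk$value == "a") RDF_TYPE
      else if (tolower(tk$value) %in% c("true", "false")) {
        paste0("\"", tolower(tk$value), "\"^^<", NS_XSD, "boolean>")
      } else stop(sprintf("parse error at line %d: unexpected name '%s' in term position",
                          tk$line, tk$value), call. = FALSE)
    },
    stop(sprintf("parse error at line %d: unexpected '%s' in term position",
                 tk$line, tk$value), call. = FALSE)
  )
}

expand_pname <- function(pname, prefixes) {
  colon <- regexpr(":", pname, fixed = TRUE)
  pfx <- substr(pname, 1L, colon - 1L)
  local <- substring(pname, colon + 1L)
  if (!pfx %in% names(prefixes)) {
    stop("undeclared prefix '", pfx, ":' in '", pname, "'", call. = FALSE)
  }
  paste0("<", prefixes[[pfx]], local, ">")
}

# --- restricted Turtle parser ----------------------------------------------

# Parses Turtle text into a tibble of s/p/o encoded terms, supporting
# @prefix/PREFIX, 'a', object lists (','), predicate-object lists (';') and
# anonymous blank-node property lists ('[ ... ]'). Collection syntax and
# multiline literals are out of scope (never produced by this package).
parse_turtle <- function(lines) {
  cur <- new_cursor(tokenize(lines))
  prefixes <- character(0)
  acc_s <- character(0); acc_p <- character(0); acc_o <- character(0)
  bn_counter <- 0L
  emit <- function(s, p, o) {
    # force all arguments first: parsing a nested [ ... ] object list appends
    # its own triples, which a lazily-evaluated `o` would clobber
    force(s); force(p); force(o)
    acc_s <<- c(acc_s, s); acc_p <<- c(acc_p, p); acc_o <<- c(acc_o, o)
  }
  parse_term_or_bnlist <- function() {
    if (cur_is_val(cur, "[")) {
      cur_next(cur)
      bn_counter <<- bn_counter + 1L
      node <- paste0("_:gen", bn_counter)
      if (!cur_is_val(cur, "]")) parse_polist(node)
      cur_expect_val(cur, "]")
      node
    } else {
      token_to_term(cur_next(cur), prefixes)
    }
  }
  parse_polist <- function(subject) {
    repeat {
      p <- if (cur_is_val(cur, "a")) { cur_next(cur); RDF_TYPE } else token_to_term(cur_next(cur), prefixes)
      repeat {
        emit(subject, p, parse_term_or_bnlist())
        if (cur_is_val(cur, ",")) cur_next(cur) else break
      }
      if (cur_is_val(cur, ";")) {
        cur_next(cur)
        if (cur_is_val(cur, ".") || cur_is_val(cur, "]")) break
      } else break
    }
  }
  while (!cur_eof(cur)) {
    tk <- cur_peek(cur)
    if (tk$type == "ATNAME" && tolower(tk$value) == "@prefix" ||
        (tk$type == "NAME" && toupper(tk$value) == "PREFIX")) {
      cur_next(cur)
      pn <- cur_next(cur)
      if (pn$type != "PNAME") cur_error(cur, "prefix name")
      iri <- cur_next(cur)
      if (iri$type != "IRIREF") cur_error(cur, "namespace IRI")
      prefixes[[sub(":$", "", pn$value)]] <- iri_value(iri$value)
      if (cur_is_val(cur, ".")) cur_next(cur)
      next
    }
    subject <- parse_term_or_bnlist()
    parse_polist(subject)
    cur_expect_val(cur, ".")
  }
  tibble::tibble(s = acc_s, p = acc_p, o = acc_o)
}
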