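#' Parse a SPARQL query
#'
#' Parses the SPARQL 1.0/1.1 subset the engine federates — SELECT and ASK
#' forms with basic graph patterns, FILTER (comparisons, boolean operators,
#' `REGEX`, `BOUND`, `STR`, `LANG`, arithmetic), OPTIONAL, UNION, SERVICE,
#' DISTINCT, ORDER BY, LIMIT and OFFSET — into an algebra tree whose leaves
#' are basic graph patterns (BGPs). Each BGP leaf receives an integer id and
#' its triple patterns contiguous ordinals from 0, in syntactic order;
#' OPTIONAL and UNION branches open new BGPs while FILTER does not, so the
#' BGP decomposition matches the usual per-group reading of the algebra.
#'
#' @param text SPARQL query string (or a character vector of lines).
#' @return An object of class `sparql_query`: a list with elements `form`
#'   (`"SELECT"` or `"ASK"`), `distinct`, `projection` (variable names, or
#'   `"*"`), `algebra` (nested list tree), `prefixes`, `limit`, `offset`,
#'   `order_by`, and `text` (the original string).
#' @export
#' @examples
#' q <- parse_query("SELECT * WHERE { ?s ?p ?o }")
#' query_patterns(q)
parse_query <- function(text) {
  text <- paste(text, collapse = "\n")
  if (!nzchar(trimws(text))) stop("parse error: empty query string", call. = FALSE)
  cur <- new_cursor(tokenize(text))
  prefixes <- character(0)
  while (cur_is_kw(cur, "PREFIX") || cur_is_kw(cur, "BASE")) {
    if (cur_is_kw(cur, "BASE")) { cur_next(cur); cur_next(cur); next }
    cur_next(cur)
    pn <- cur_next(cur)
    if (pn$type != "PNAME") cur_error(cur, "prefix name ending in ':'")
    iri <- cur_next(cur)
    if (iri$type != "IRIREF") cur_error(cur, "namespace IRI")
    prefixes[[sub(":$", "", pn$value)]] <- iri_value(iri$value)
  }
  form <- NULL; distinct <- FALSE; projection <- character(0)
  if (cur_is_kw(cur, "SELECT")) {
    form <- "SELECT"
    cur_next(cur)
    if (cur_is_kw(cur, "DISTINCT")) { distinct <- TRUE; cur_next(cur) }
    if (cur_is_kw(cur, "REDUCED")) cur_next(cur)
    if (cur_is_val(cur, "*")) {
      projection <- "*"
      cur_next(cur)
    } else {
      while (!cur_eof(cur) && cur_peek(cur)$type == "VAR") {
        projection <- c(projection, substring(cur_next(cur)$value, 2L))
      }
      if (length(projection) == 0) cur_error(cur, "projection variables or '*'")
    }
    if (cur_is_kw(cur, "WHERE")) cur_next(cur)
  } else if (cur_is_kw(cur, "ASK")) {
    form <- "ASK"
    cur_next(cur)
    if (cur_is_kw(cur, "WHERE")) cur_next(cur)
  } else {
    cur_error(cur, "SELECT or ASK")
  }
  algebra <- parse_group_or_union(cur, prefixes)
  limit <- NA_integer_; offset <- NA_integer_
  order_by <- tibble::tibble(var = character(), desc = logical())
  repeat {
    if (cur_is_kw(cur, "ORDER")) {
      cur_next(cur); cur_expect_kw(cur, "BY")
      repeat {
        desc <- FALSE
        if (cur_is_kw(cur, "ASC") || cur_is_kw(cur, "DESC")) {
          desc <- cur_is_kw(cur, "DESC")
          cur_next(cur); cur_expect_val(cur, "(")
          v <- cur_next(cur)
          if (v$type != "VAR") cur_error(cur, "variable")
          cur_expect_val(cur, ")")
          order_by <- dplyr::bind_rows(order_by, tibble::tibble(var = substring(v$value, 2L), desc = desc))
        } else if (!cur_eof(cur) && cur_peek(cur)$type == "VAR") {
          order_by <- dplyr::bind_rows(order_by, tibble::tibble(var = substring(cur_next(cur)$value, 2L), desc = FALSE))
        } else break
      }
    } else if (cur_is_kw(cur, "LIMIT")) {
      cur_next(cur)
      limit <- as.integer(cur_next(cur)$value)
    } else if (cur_is_kw(cur, "OFFSET")) {
      cur_next(cur)
      offset <- as.integer(cur_next(cur)$value)
    } else break
  }
  if (!cur_eof(cur)) cur_error(cur, "end of query")
  q <- structure(
    list(form = form, distinct = distinct, projection = projection,
         algebra = algebra, prefixes = prefixes, limit = limit,
         offset = offset, order_by = order_by, text = text),
    class = "sparql_query"
  )
  q$algebra <- number_bgps(q$algebra)
  q
}

# --- group / algebra parsing -----------------------------------------------

parse_group_or_union <- function(cur, prefixes) {
  first <- parse_group(cur, prefixes)
  if (!cur_is_kw(cur, "UNION")) return(first)
  parts <- list(first)
  while (cur_is_kw(cur, "UNION")) {
    cur_next(cur)
    parts <- c(parts, list(parse_group(cur, prefixes)))
  }
  list(type = "union", parts = parts)
}

parse_group <- function(cur, prefixes) {
  cur_expect_val(cur, "{")
  parts <- list()
  filters <- list()
  cur_s <- character(0); cur_p <- character(0); cur_o <- character(0)
  flush_bgp <- function() {
    if (length(cur_s) > 0) {
      parts[[length(parts) + 1L]] <<- list(
        type = "bgp", id = NA_integer_,
        patterns = tibble::tibble(s = cur_s, p = cur_p, o = cur_o)
      )
      cur_s <<- character(0); cur_p <<- character(0); cur_o <<- character(0)
    }
  }
  combine <- function(ps) {
    if (length(ps) == 0) list(type = "unit")
    else if (length(ps) == 1) ps[[1]]
    else list(type = "join", parts = ps)
  }
  repeat {
    if (cur_is_val(cur, "}")) { cur_next(cur); break }
    if (cur_is_val(cur, ".")) { cur_next(cur); next }
    if (cur_is_kw(cur, "FILTER")) {
      cur_next(cur)
      filters[[length(filters) + 1L]] <- parse_bracketted_or_call(cur, prefixes)
    } else if (cur_is_kw(cur, "OPTIONAL")) {
      cur_next(cur)
      rhs <- parse_group(cur, prefixes)
      flush_bgp()
      left <- combine(parts)
      parts <- list(list(type = "optional", left = left, right = rhs))
    } else if (cur_is_kw(cur, "SERVICE")) {
      cur_next(cur)
      silent <- FALSE
      if (cur_is_kw(cur, "SILENT")) { silent <- TRUE; cur_next(cur) }
      ep <- token_to_term(cur_next(cur), prefixes)
      inner <- parse_group(cur, prefixes)
      flush_bgp()
      parts[[length(parts) + 1L]] <- list(type = "service", endpoint = ep,
                                          silent = silent, inner = inner)
    } else if (cur_is_val(cur, "{")) {
      flush_bgp()
      parts[[length(parts) + 1L]] <- parse_group_or_union(cur, prefixes)
    } else {
      # a triples block statement: subject predicate-object list
      s <- token_to_term(cur_next(cur), prefixes)
      repeat {
        p <- token_to_term(cur_next(cur), prefixes)
        if (!term_kind(p) %in% c("iri", "variable")) {
          stop("parse error: predicate must be an IRI or variable, found ", p, call. = FALSE)
        }
        repeat {
          o <- token_to_term(cur_next(cur), prefixes)
          cur_s <- c(cur_s, s); cur_p <- c(cur_p, p); cur_o <- c(cur_o, o)
          if (cur_is_val(cur, ",")) cur_next(cur) else break
        }
        if (cur_is_val(cur, ";")) {
          cur_next(cur)
          if (cur_is_val(cur, ".") || cur_is_val(cur, "}")) break
        } else break
      }
      if (cur_is_val(cur, ".")) cur_next(cur)
    }
  }
  flush_bgp()
  node <- combine(parts)
  for (f in filters) node <- list(type = "filter", expr = f, inner = node)
  node
}

# --- filter expressions -----------------------------------------------------

parse_bracketted_or_call <- function(cur, prefixes) {
  if (cur_is_val(cur, "(")) {
    cur_next(cur)
    e <- parse_expr(cur, prefixes)
    cur_expect_val(cur, ")")
    e
  } else {
    parse_primary(cur, prefixes)
  }
}

parse_expr <- function(cur, prefixes) {
  left <- parse_and(cur, prefixes)
  while (cur_is_val(cur, "||")) {
    cur_next(cur)
    left <- list(type = "op", op = "||", args = list(left, parse_and(cur, prefixes)))
  }
  left
}

parse_and <- function(cur, prefixes) {
  left <- parse_relational(cur, prefixes)
  while (cur_is_val(cur, "&&")) {
    cur_next(cur)
    left <- list(type = "op", op = "&&", args = list(left, parse_relational(cur, prefixes)))
  }
  left
}

parse_relational <- function(cur, prefixes) {
  left <- parse_additive(cur, prefixes)
  ops <- c("=", "!=", "<", ">", "<=", ">=")
  tk <- cur_peek(cur)
  if (!is.null(tk) && tk$value %in% ops && tk$type %in% c("PUNCT", "OP2")) {
    cur_next(cur)
    left <- list(type = "op", op = tk$value, args = list(left, parse_additive(cur, prefixes)))
  }
  left
}

parse_additive <- function(cur, prefixes) {
  left <- parse_multiplicative(cur, prefixes)
  repeat {
    if (cur_is_val(cur, "+") || cur_is_val(cur, "-")) {
      op <- cur_next(cur)$value
      left <- list(type = "op", op = op, args = list(left, parse_multiplicative(cur, prefixes)))
    } else break
  }
  left
}

parse_multiplicative <- function(cur, prefixes) {
  left <- parse_unary(cur, prefixes)
  repeat {
    if (cur_is_val(cur, "*") || cur_is_val(cur, "/")) {
      op <- cur_next(cur)$value
      left <- list(type = "op", op = op, args = list(left, parse_unary(cur, prefixes)))
    } else break
  }
  left
}

parse_unary <- function(cur, prefixes) {
  if (cur_is_val(cur, "!")) {
    cur_next(cur)
    return(list(type = "op", op = "!", args = list(parse_unary(cur, prefixes))))
  }
  parse_primary(cur, prefixes)
}

BUILTIN_FNS <- c("regex", "bound", "str", "lang", "datatype", "isiri", "isliteral", "contains", "strstarts")

parse_primary <- function(cur, prefixes) {
  if (cur_is_val(cur, "(")) {
    cur_next(cur)
    e <- parse_expr(cur, prefixes)
    cur_expect_val(cur, ")")
    return(e)
  }
  tk <- cur_peek(cur)
  if (is.null(tk)) cur_error(cur, "expression")
  if (tk$type == "NAME" && tolower(tk$value) %in% BUILTIN_FNS && cur_is_val(cur, "(", ahead = 1L)) {
    fn <- tolower(cur_next(cur)$value)
    cur_expect_val(cur, "(")
    args <- list()
    if (!cur_is_val(cur, ")")) {
      repeat {
        args <- c(args, list(parse_expr(cur, prefixes)))
        if (cur_is_val(cur, ",")) cur_next(cur) else break
      }
    }
    cur_expect_val(cur, ")")
    return(list(type = "call", fn = fn, args = args))
  }
  list(type = "term", term = token_to_term(cur_next(cur), prefixes))
}

# --- BGP numbering and enumeration -----------------------------------------

number_bgps <- function(node) {
  counter <- 0L
  walk <- function(n) {
    switch(n$type,
      bgp = {
        n$id <- counter
        counter <<- counter + 1L
        n$patterns$ordinal <- seq_len(nrow(n$patterns)) - 1L
        n
      },
      join = ,
      union = { n$parts <- lapply(n$parts, walk); n },
      optional = { n$left <- walk(n$left); n$right <- walk(n$right); n },
      filter = { n$inner <- walk(n$inner); n },
      service = { n$inner <- walk(n$inner); n },
      unit = n,
      stop("unknown algebra node type: ", n$type)
    )
  }
  walk(node)
}

#' Enumerate the triple patterns of a parsed query
#'
#' @param q A `sparql_query` (or an algebra node).
#' @return A tibble with one row per triple pattern in syntactic order:
#'   `bgp_id`, `ordinal`, and the encoded `s`, `p`, `o` terms.
#' @export
query_patterns <- function(q) {
  node <- if (inherits(q, "sparql_query")) q$algebra else q
  acc <- list()
  walk <- function(n) {
    switch(n$type,
      bgp = {
        acc[[length(acc) + 1L]] <<- tibble::tibble(
          bgp_id = n$id, ordinal = n$patterns$ordinal,
          s = n$patterns$s, p = n$patterns$p, o = n$patterns$o
        )
      },
      join = ,
      union = lapply(n$parts, walk),
      optional = { walk(n$left); walk(n$right) },
      filter = ,
      service = walk(n$inner),
      unit = NULL
    )
    invisible(NULL)
  }
  walk(node)
  if (length(acc) == 0) {
    return(tibble::tibble(bgp_id = integer(), ordinal = integer(),
                          s = character(), p = character(), o = character()))
  }
  dplyr::bind_rows(acc)
}

# variables appearing in an algebra node (bindable positions only)
node_variables <- function(node) {
  pats <- query_patterns(node)
  terms <- c(pats$s, pats$p, pats$o)
  unique(var_name(terms[is_varlike_term(terms)]))
}

expr_variables <- function(expr) {
  switch(expr$type,
    term = if (is_varlike_term(expr$term)) var_name(expr$term) else character(0),
    op = unique(unlist(lapply(expr$args, expr_variables))),
    call = unique(unlist(lapply(expr$args, expr_variables))),
    character(0)
  )
}

#' @export
print.sparql_query <- function(x, ...) {
  pats <- query_patterns(x)
  cat("<sparql_query> ", x$form,
      if (x$distinct) " DISTINCT", ", ",
      length(unique(pats$bgp_id)), " BGP(s), ",
      nrow(pats), " triple pattern(s)\n", sep = "")
  cat(serialize_query(x), "\n")
  invisible(x)
}
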