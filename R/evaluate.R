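# SPARQL algebra evaluation over in-memory triple tables.
#
# Solution multisets are tibbles with one character column per variable
# (encoded terms; NA = unbound). Multiplicity is preserved everywhere:
# BGP joins are many-to-many equijoins, UNION is row concatenation,
# OPTIONAL is a compatibility left join, DISTINCT is applied only at
# projection when the query asks for it.

unit_solution <- function() tibble::new_tibble(list(), nrow = 1L)
empty_solution <- function() tibble::new_tibble(list(), nrow = 0L)

merge_solutions <- function(a, b, type = c("inner", "left")) {
  type <- match.arg(type)
  common <- intersect(names(a), names(b))
  if (length(common) == 0) {
    if (type == "left" && nrow(b) == 0) {
      for (nm in setdiff(names(b), names(a))) a[[nm]] <- NA_character_
      return(a)
    }
    return(dplyr::cross_join(a, b))
  }
  has_na <- anyNA(a[common]) || anyNA(b[common])
  if (!has_na) {
    if (type == "inner") {
      return(dplyr::inner_join(a, b, by = common, relationship = "many-to-many"))
    }
    return(dplyr::left_join(a, b, by = common, relationship = "many-to-many"))
  }
  # generic compatibility join (unbound matches anything); only reached when
  # OPTIONAL has produced NAs, so inputs are small
  a2 <- dplyr::mutate(a, .aid = dplyr::row_number())
  bonly <- setdiff(names(b), names(a))
  j <- dplyr::cross_join(a2, b, suffix = c(".x", ".y"))
  keep <- rep(TRUE, nrow(j))
  for (cc in common) {
    x <- j[[paste0(cc, ".x")]]; y <- j[[paste0(cc, ".y")]]
    keep <- keep & (is.na(x) | is.na(y) | x == y)
  }
  j <- j[keep, , drop = FALSE]
  for (cc in common) {
    j[[cc]] <- dplyr::coalesce(j[[paste0(cc, ".x")]], j[[paste0(cc, ".y")]])
    j[[paste0(cc, ".x")]] <- NULL
    j[[paste0(cc, ".y")]] <- NULL
  }
  if (type == "left") {
    unmatched <- dplyr::anti_join(a2, j[, ".aid", drop = FALSE], by = ".aid")
    for (nm in bonly) unmatched[[nm]] <- NA_character_
    j <- dplyr::bind_rows(j, unmatched)
  }
  j$.aid <- NULL
  j
}

eval_node <- function(node, graph, svc = NULL) {
  switch(node$type,
    unit = unit_solution(),
    bgp = {
      sols <- unit_solution()
      for (i in seq_len(nrow(node$patterns))) {
        m <- match_pattern(graph, node$patterns$s[i], node$patterns$p[i], node$patterns$o[i])
        sols <- merge_solutions(sols, m)
        if (nrow(sols) == 0 && i < nrow(node$patterns)) {
          # still need the remaining pattern variables as empty columns
          rest <- node$patterns[(i + 1):nrow(node$patterns), ]
          terms <- c(rest$s, rest$p, rest$o)
          for (v in unique(var_name(terms[is_varlike_term(terms)]))) {
            if (!v %in% names(sols)) sols[[v]] <- character(0)
          }
          break
        }
      }
      sols
    },
    join = Reduce(merge_solutions, lapply(node$parts, eval_node, graph = graph, svc = svc)),
    union = dplyr::bind_rows(lapply(node$parts, eval_node, graph = graph, svc = svc)),
    optional = merge_solutions(eval_node(node$left, graph, svc),
                               eval_node(node$right, graph, svc), type = "left"),
    filter = {
      sols <- eval_node(node$inner, graph, svc)
      if (nrow(sols) == 0) return(sols)
      keep <- vapply(seq_len(nrow(sols)), function(i) {
        isTRUE(ebv(eval_expr_row(node$expr, sols[i, , drop = FALSE])))
      }, logical(1))
      sols[keep, , drop = FALSE]
    },
    service = {
      if (is.null(svc)) {
        stop("SERVICE clause encountered but no endpoint resolver supplied", call. = FALSE)
      }
      svc(node$endpoint, node$inner, node$silent)
    },
    stop("cannot evaluate node of type ", node$type)
  )
}

# --- filter expression values ----------------------------------------------

val_err <- list(kind = "err", v = NA)

term_to_value <- function(term, row) {
  if (is_varlike_term(term)) {
    nm <- var_name(term)
    if (!nm %in% names(row)) return(val_err)
    enc <- row[[nm]]
    if (is.na(enc)) return(val_err)
    return(encoded_to_value(enc))
  }
  encoded_to_value(term)
}

encoded_to_value <- function(enc) {
  k <- term_kind(enc)
  if (k == "iri") return(list(kind = "iri", v = iri_value(enc)))
  if (k == "literal") {
    parts <- literal_parts(enc)
    if (!is.na(parts$datatype) && parts$datatype == paste0(NS_XSD, "boolean")) {
      return(list(kind = "bool", v = identical(parts$lexical, "true")))
    }
    if (!is.na(parts$datatype) && parts$datatype %in% XSD_NUMERIC) {
      return(list(kind = "num", v = as.numeric(parts$lexical)))
    }
    return(list(kind = "str", v = parts$lexical, lang = parts$lang))
  }
  val_err
}

ebv <- function(val) {
  switch(val$kind,
    bool = val$v,
    num = val$v != 0,
    str = nzchar(val$v),
    NA
  )
}

eval_expr_row <- function(expr, row) {
  switch(expr$type,
    term = term_to_value(expr$term, row),
    op = eval_op(expr, row),
    call = eval_call(expr, row),
    val_err
  )
}

eval_op <- function(expr, row) {
  op <- expr$op
  if (op %in% c("&&", "||")) {
    l <- ebv(eval_expr_row(expr$args[[1]], row))
    r <- ebv(eval_expr_row(expr$args[[2]], row))
    v <- if (op == "&&") {
      if (isFALSE(l) || isFALSE(r)) FALSE else if (isTRUE(l) && isTRUE(r)) TRUE else NA
    } else {
      if (isTRUE(l) || isTRUE(r)) TRUE else if (isFALSE(l) && isFALSE(r)) FALSE else NA
    }
    if (is.na(v)) return(val_err)
    return(list(kind = "bool", v = v))
  }
  if (op == "!") {
    v <- ebv(eval_expr_row(expr$args[[1]], row))
    if (is.na(v)) return(val_err)
    return(list(kind = "bool", v = !v))
  }
  l <- eval_expr_row(expr$args[[1]], row)
  r <- eval_expr_row(expr$args[[2]], row)
  if (l$kind == "err" || r$kind == "err") return(val_err)
  if (op %in% c("+", "-", "*", "/")) {
    if (l$kind != "num" || r$kind != "num") return(val_err)
    return(list(kind = "num", v = switch(op, "+" = l$v + r$v, "-" = l$v - r$v,
                                         "*" = l$v * r$v, "/" = l$v / r$v)))
  }
  # comparisons
  if (l$kind != r$kind) return(val_err)
  if (l$kind %in% c("iri", "bool") && !op %in% c("=", "!=")) return(val_err)
  cmpv <- switch(op,
    "=" = identical(l$v, r$v),
    "!=" = !identical(l$v, r$v),
    "<" = l$v < r$v,
    ">" = l$v > r$v,
    "<=" = l$v <= r$v,
    ">=" = l$v >= r$v,
    return(val_err)
  )
  list(kind = "bool", v = cmpv)
}

eval_call <- function(expr, row) {
  fn <- expr$fn
  if (fn == "bound") {
    arg <- expr$args[[1]]
    if (arg$type != "term" || !is_varlike_term(arg$term)) return(val_err)
    nm <- var_name(arg$term)
    return(list(kind = "bool", v = nm %in% names(row) && !is.na(row[[nm]])))
  }
  vals <- lapply(expr$args, eval_expr_row, row = row)
  if (any(vapply(vals, function(v) v$kind == "err", logical(1)))) return(val_err)
  as_str <- function(v) {
    switch(v$kind, str = v$v, iri = v$v,
           num = format(v$v, scientific = FALSE, trim = TRUE),
           bool = if (v$v) "true" else "false", NA_character_)
  }
  switch(fn,
    regex = {
      flags <- if (length(vals) >= 3) as_str(vals[[3]]) else ""
      list(kind = "bool",
           v = grepl(as_str(vals[[2]]), as_str(vals[[1]]),
                     ignore.case = grepl("i", flags, fixed = TRUE), perl = TRUE))
    },
    str = list(kind = "str", v = as_str(vals[[1]]), lang = NA_character_),
    lang = list(kind = "str",
                v = if (!is.null(vals[[1]]$lang) && !is.na(vals[[1]]$lang)) vals[[1]]$lang else "",
                lang = NA_character_),
    datatype = val_err,
    isiri = list(kind = "bool", v = vals[[1]]$kind == "iri"),
    isliteral = list(kind = "bool", v = vals[[1]]$kind %in% c("str", "num", "bool")),
    contains = list(kind = "bool", v = grepl(as_str(vals[[2]]), as_str(vals[[1]]), fixed = TRUE)),
    strstarts = list(kind = "bool", v = startsWith(as_str(vals[[1]]), as_str(vals[[2]]))),
    val_err
  )
}

# --- projection and solution modifiers -------------------------------------

project_solutions <- function(q, sols) {
  vars <- if (identical(q$projection, "*")) {
    nv <- node_variables(q$algebra)
    nv[!startsWith(nv, ".")]
  } else q$projection
  for (v in vars) if (!v %in% names(sols)) sols[[v]] <- rep(NA_character_, nrow(sols))
  out <- sols[, vars, drop = FALSE]
  if (nrow(q$order_by) > 0) {
    keys <- lapply(seq_len(nrow(q$order_by)), function(i) {
      v <- q$order_by$var[i]
      k <- if (v %in% names(out)) out[[v]] else rep(NA_character_, nrow(out))
      if (q$order_by$desc[i]) dplyr::desc(k) else k
    })
    out <- out[do.call(order, c(keys, list(method = "radix"))), , drop = FALSE]
  }
  if (q$distinct) out <- dplyr::distinct(out)
  off <- if (is.na(q$offset)) 0L else q$offset
  if (off > 0L) out <- out[-seq_len(min(off, nrow(out))), , drop = FALSE]
  if (!is.na(q$limit)) out <- utils::head(out, q$limit)
  tibble::as_tibble(out)
}

#' Evaluate a SPARQL query over a local graph
#'
#' Runs a query directly against one in-memory triple table — the
#' "single central store" evaluation that federated execution must
#' reproduce. SERVICE clauses are resolved through `svc` when supplied
#' (see [execute_query()] for federated execution with provenance).
#'
#' @param query SPARQL text or a `sparql_query`.
#' @param graph A triple tibble ([rdf_graph()]).
#' @param svc Optional resolver `function(endpoint_iri, algebra_node, silent)`
#'   returning a solution tibble.
#' @return For SELECT, a tibble of bindings (encoded terms, one column per
#'   projected variable); for ASK, a logical scalar.
#' @export
#' @examples
#' g <- rdf_graph(rdf_iri("http://x/a"), RDF_TYPE, rdf_iri("http://x/C"))
#' run_sparql("SELECT * WHERE { ?s ?p ?o }", g)
run_sparql <- function(query, graph, svc = NULL) {
  q <- if (is.character(query)) parse_query(query) else query
  sols <- eval_node(q$algebra, graph, svc)
  if (q$form == "ASK") return(nrow(sols) > 0)
  project_solutions(q, sols)
}
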