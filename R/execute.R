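# query-scoped provenance cache (package state); records expire after the
# retention window or when the same session issues its next query
.prov_cache <- new.env(parent = emptyenv())

PROVENANCE_RETENTION_MS <- 10 * 60 * 1000

#' Execute a (rewritten) federated query
#'
#' Evaluates a SPARQL 1.1 query whose SERVICE blocks are resolved through
#' the endpoint registry. Every SERVICE invocation is wrapped in
#' instrumentation — start/end timestamps, elapsed time, number of solution
#' rows returned, and status — and the per-service records are collected
#' into a query provenance object, cached for later retrieval with
#' [get_provenance()].
#'
#' A SERVICE against a down endpoint contributes no solutions and a
#' `status = "down"` record (partial results), or aborts execution under
#' `strict = TRUE`. Patterns outside SERVICE blocks are evaluated against
#' an empty default graph, as in a pure federator.
#'
#' @param rq A `rewritten_query`, `sparql_query`, or SPARQL 1.1 text.
#' @param registry An [endpoint_registry()] resolving every SERVICE
#'   endpoint.
#' @param session Caller-supplied session key: issuing a new query evicts
#'   the session's previous provenance record.
#' @param strict Abort on a down endpoint instead of returning partial
#'   results.
#' @param clock Millisecond clock function (injectable for tests).
#' @param query_id Identifier for the provenance record; generated when
#'   omitted.
#' @return A `federated_result`: list with `results` (solution tibble, or
#'   logical for ASK) and `provenance` (class `query_provenance`).
#' @export
execute_query <- function(rq, registry, session = "default", strict = FALSE,
                          clock = wall_clock_ms, query_id = NULL) {
  q <- if (inherits(rq, "rewritten_query")) rq$query
       else if (is.character(rq)) parse_query(rq)
       else rq
  if (is.null(query_id)) {
    .prov_cache$counter <- (.prov_cache$counter %||% 0L) + 1L
    query_id <- sprintf("q%06d", .prov_cache$counter)
  }
  records <- list()
  svc <- function(endpoint, inner, silent) {
    url <- iri_value(endpoint)
    start <- clock()
    ans <- tryCatch(endpoint_evaluate(registry, url, inner), error = function(e) e)
    end <- clock()
    if (inherits(ans, "error")) {
      down <- grepl("endpoint down|unknown endpoint", conditionMessage(ans))
      records[[length(records) + 1L]] <<- tibble::tibble(
        endpoint = url, start_ms = start, end_ms = end, elapsed_ms = end - start,
        result_count = 0L, status = if (down) "down" else "error",
        message = conditionMessage(ans))
      if (strict && !silent) {
        stop("SERVICE ", url, " failed: ", conditionMessage(ans), call. = FALSE)
      }
      # partial results: the failed service contributes no solutions
      vars <- node_variables(inner)
      out <- tibble::new_tibble(stats::setNames(rep(list(character(0)), length(vars)), vars),
                                nrow = 0L)
      return(out)
    }
    records[[length(records) + 1L]] <<- tibble::tibble(
      endpoint = url, start_ms = start, end_ms = end, elapsed_ms = end - start,
      result_count = nrow(ans), status = "ok", message = NA_character_)
    ans
  }
  t0 <- clock()
  sols <- eval_node(q$algebra, rdf_graph(), svc)
  results <- if (q$form == "ASK") nrow(sols) > 0 else project_solutions(q, sols)
  t1 <- clock()
  services <- if (length(records)) dplyr::bind_rows(records) else
    tibble::tibble(endpoint = character(), start_ms = numeric(), end_ms = numeric(),
                   elapsed_ms = numeric(), result_count = integer(),
                   status = character(), message = character())
  prov <- structure(
    list(query_id = query_id, session = session, services = services,
         total_elapsed_ms = t1 - t0, created_at = t0,
         retention_deadline = t0 + PROVENANCE_RETENTION_MS),
    class = "query_provenance"
  )
  # same-session eviction, then cache the new record
  for (id in ls(.prov_cache)) {
    rec <- .prov_cache[[id]]
    if (inherits(rec, "query_provenance") && identical(rec$session, session)) {
      rm(list = id, envir = .prov_cache)
    }
  }
  assign(query_id, prov, envir = .prov_cache)
  structure(list(results = results, provenance = prov), class = "federated_result")
}

#' Retrieve a cached provenance record
#'
#' Records live for ten minutes after query execution, or until the same
#' session runs its next query, whichever comes first.
#'
#' @param query_id Identifier returned in the `query_provenance`.
#' @param clock Millisecond clock (injectable for expiry tests).
#' @return The `query_provenance`, or an error of class
#'   `sparqlfed_provenance_not_found` when unknown or expired.
#' @export
get_provenance <- function(query_id, clock = wall_clock_ms) {
  rec <- .prov_cache[[query_id]]
  if (!is.null(rec) && clock() > rec$retention_deadline) {
    rm(list = query_id, envir = .prov_cache)
    rec <- NULL
  }
  if (is.null(rec)) {
    stop(structure(
      class = c("sparqlfed_provenance_not_found", "error", "condition"),
      list(message = paste0("no provenance record for query id '", query_id,
                            "' (unknown or expired)"),
           call = NULL)))
  }
  rec
}

#' @export
print.query_provenance <- function(x, ...) {
  cat("<query_provenance> ", x$query_id, " (session ", x$session, ")\n",
      sprintf("  total %.1f ms, %d service invocation(s)\n",
              x$total_elapsed_ms, nrow(x$services)), sep = "")
  print(x$services[, c("endpoint", "elapsed_ms", "result_count", "status")])
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.query_provenance <- function(x, ...) x$services

#' @exportS3Method generics::glance
glance.query_provenance <- function(x, ...) {
  tibble::tibble(
    query_id = x$query_id, n_services = nrow(x$services),
    total_elapsed_ms = x$total_elapsed_ms,
    results_returned = sum(x$services$result_count),
    n_down = sum(x$services$status == "down"),
    n_error = sum(x$services$status == "error")
  )
}

#' @export
print.federated_result <- function(x, ...) {
  cat("<federated_result>\n")
  print(x$results)
  cat(sprintf("provenance: %s, %d service invocation(s), %.1f ms\n",
              x$provenance$query_id, nrow(x$provenance$services),
              x$provenance$total_elapsed_ms))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.federated_result <- function(x, ...) {
  if (is.logical(x$results)) tibble::tibble(ask = x$results) else x$results
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- result writers ---------------------------------------------------------

#' Write query results in standard formats
#'
#' Solution tibbles can be exported as text, CSV, TSV, JSON, Turtle or XML.
#' CSV/TSV/JSON/text carry decoded values (IRIs bare, literals as their
#' lexical forms); Turtle emits one result-set resource per row with one
#' property per variable; XML follows the SPARQL query results format.
#'
#' @param results A solution tibble (from [execute_query()] or
#'   [run_sparql()]).
#' @param path Output file.
#' @param format One of `"txt"`, `"csv"`, `"tsv"`, `"json"`, `"ttl"`,
#'   `"xml"`.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path,
                          format = c("csv", "tsv", "json", "ttl", "xml", "txt")) {
  format <- match.arg(format)
  decode <- function(x) {
    vapply(x, function(v) {
      if (is.na(v)) return(NA_character_)
      if (startsWith(v, "<")) iri_value(v)
      else if (startsWith(v, "\"")) literal_parts(v)$lexical
      else v
    }, character(1))
  }
  plain <- dplyr::mutate(results, dplyr::across(dplyr::everything(), decode))
  switch(format,
    csv = readr::write_csv(plain, path, na = ""),
    tsv = readr::write_tsv(plain, path, na = ""),
    txt = writeLines(c(paste(names(plain), collapse = "\t"),
                       apply(plain, 1, paste, collapse = "\t")), path),
    json = jsonlite::write_json(plain, path, dataframe = "rows", na = "null",
                                auto_unbox = TRUE, pretty = TRUE),
    ttl = {
      n <- nrow(results)
      rows <- rdf_iri(sprintf("http://purl.org/net/sparqlfed/result#row%d", seq_len(n)))
      g <- purrr::map_dfr(names(results), function(v) {
        keep <- !is.na(results[[v]])
        tibble::tibble(s = rows[keep],
                       p = rdf_iri(paste0("http://purl.org/net/sparqlfed/result#", v)),
                       o = results[[v]][keep])
      })
      write_graph(if (nrow(g)) g else rdf_graph(), path, format = "turtle")
    },
    xml = {
      doc <- xml2::xml_new_root("sparql", xmlns = "http://www.w3.org/2005/sparql-results#")
      head_node <- xml2::xml_add_child(doc, "head")
      for (v in names(results)) xml2::xml_add_child(head_node, "variable", name = v)
      res_node <- xml2::xml_add_child(doc, "results")
      for (i in seq_len(nrow(results))) {
        rn <- xml2::xml_add_child(res_node, "result")
        for (v in names(results)) {
          val <- results[[v]][i]
          if (is.na(val)) next
          b <- xml2::xml_add_child(rn, "binding", name = v)
          if (startsWith(val, "<")) {
            xml2::xml_add_child(b, "uri", iri_value(val))
          } else {
            parts <- literal_parts(val)
            lt <- xml2::xml_add_child(b, "literal", parts$lexical)
            if (!is.na(parts$datatype)) xml2::xml_set_attr(lt, "datatype", parts$datatype)
            if (!is.na(parts$lang)) xml2::xml_set_attr(lt, "xml:lang", parts$lang)
          }
        }
      }
      xml2::write_xml(doc, path)
    }
  )
  invisible(path)
}
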