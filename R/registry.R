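#' Endpoint registry
#'
#' Maps endpoint URLs to query capabilities. An endpoint is an in-process
#' RDF graph plus a simulated latency and an up/down flag, which makes
#' availability logic and lowest-latency mirror selection deterministic and
#' testable without a network; a remote SPARQL-protocol transport can be
#' plugged in by registering a `resolver` function instead of a graph.
#' The registry also owns the availability graph (`EndpointData`): every
#' [check_availability()] cycle records latency, up/down status,
#' initialisation state and check time per endpoint as RDF, queryable with
#' [run_sparql()] via [endpoint_data_graph()].
#'
#' @return `endpoint_registry()` returns an empty registry.
#' @export
#' @examples
#' reg <- endpoint_registry()
#' register_endpoint(reg, "http://example.org/sparql", rdf_graph(), latency_ms = 12)
endpoint_registry <- function() {
  env <- new.env(parent = emptyenv())
  env$endpoints <- list()
  env$endpoint_data <- rdf_graph()
  env$ask_count <- 0L
  structure(env, class = "endpoint_registry")
}

#' @rdname endpoint_registry
#' @param registry An `endpoint_registry`.
#' @param url Endpoint URL.
#' @param graph Triple tibble served by the endpoint.
#' @param latency_ms Simulated round-trip latency.
#' @param up Availability flag.
#' @param resolver Optional `function(query_type, ...)` replacing in-process
#'   evaluation (remote transport hook).
#' @export
register_endpoint <- function(registry, url, graph = rdf_graph(), latency_ms = 5,
                              up = TRUE, resolver = NULL) {
  registry$endpoints[[url]] <- list(url = url, graph = graph,
                                    latency_ms = latency_ms, up = up,
                                    initialized = TRUE, resolver = resolver)
  invisible(registry)
}

registry_get <- function(registry, url) registry$endpoints[[url]]

#' @rdname endpoint_registry
#' @export
registry_urls <- function(registry) names(registry$endpoints)

#' @rdname endpoint_registry
#' @export
set_endpoint_up <- function(registry, url, up) {
  if (is.null(registry$endpoints[[url]])) stop("unknown endpoint: ", url, call. = FALSE)
  registry$endpoints[[url]]$up <- up
  invisible(registry)
}

#' @rdname endpoint_registry
#' @export
deregister_endpoint <- function(registry, url) {
  registry$endpoints[[url]] <- NULL
  invisible(registry)
}

#' @export
print.endpoint_registry <- function(x, ...) {
  cat("<endpoint_registry> ", length(x$endpoints), " endpoint(s)\n", sep = "")
  for (ep in x$endpoints) {
    cat("  ", ep$url, "  [", if (ep$up) "up" else "down", ", ",
        ep$latency_ms, " ms, ", nrow(ep$graph), " triples]\n", sep = "")
  }
  invisible(x)
}

# boolean ASK of one triple pattern against one endpoint; counts the request
endpoint_ask <- function(registry, url, s, p, o) {
  ep <- registry_get(registry, url)
  if (is.null(ep)) stop("unknown endpoint: ", url, call. = FALSE)
  registry$ask_count <- registry$ask_count + 1L
  if (!ep$up) return(structure(FALSE, down = TRUE))
  if (!is.null(ep$resolver)) return(ep$resolver("ask", s = s, p = p, o = o))
  graph_ask(ep$graph, s, p, o)
}

# full evaluation of an algebra node at one endpoint
endpoint_evaluate <- function(registry, url, node) {
  ep <- registry_get(registry, url)
  if (is.null(ep)) stop("unknown endpoint: ", url, call. = FALSE)
  if (!ep$up) stop("endpoint down: ", url, call. = FALSE)
  if (!is.null(ep$resolver)) return(ep$resolver("evaluate", node = node))
  eval_node(node, ep$graph, svc = NULL)
}

# --- availability monitoring -----------------------------------------------

#' Check endpoint availability
#'
#' Preemptively probes each URL with a trivial ASK, records latency and
#' up/down status, and updates the registry's availability graph so the same
#' information is retrievable by SPARQL over [endpoint_data_graph()].
#' Unknown URLs become `up = FALSE` records; probe failures never raise.
#'
#' @param urls Endpoint URLs to check; defaults to every registered endpoint.
#' @param registry An [endpoint_registry()].
#' @param clock A zero-argument function returning the current time in
#'   milliseconds (injectable for tests).
#' @return A tibble with one row per URL: `url`, `latency_ms` (NA when
#'   down), `up`, `initialized`, `last_checked`.
#' @export
check_availability <- function(urls = registry_urls(registry), registry,
                               clock = wall_clock_ms) {
  now <- clock()
  statuses <- purrr::map_dfr(urls, function(u) {
    ep <- registry_get(registry, u)
    if (is.null(ep) || !ep$up) {
      return(tibble::tibble(url = u, latency_ms = NA_real_, up = FALSE,
                            initialized = !is.null(ep) && isTRUE(ep$initialized),
                            last_checked = now))
    }
    registry$ask_count <- registry$ask_count + 1L
    tibble::tibble(url = u, latency_ms = as.numeric(ep$latency_ms), up = TRUE,
                   initialized = isTRUE(ep$initialized), last_checked = now)
  })
  # rewrite this cycle's records in the availability graph
  sf <- function(local) rdf_iri(paste0(SFED_NS, local))
  keep <- !(registry$endpoint_data$s %in% rdf_iri(urls))
  records <- purrr::map_dfr(seq_len(nrow(statuses)), function(i) {
    r <- statuses[i, ]
    subj <- rdf_iri(r$url)
    tibble::tibble(
      s = subj,
      p = c(sf("latency"), sf("up"), sf("initialized"), sf("lastChecked"), sf("endpointURL")),
      o = c(
        if (is.na(r$latency_ms)) rdf_literal("unknown")
        else rdf_literal(format(r$latency_ms, scientific = FALSE, trim = TRUE),
                         datatype = paste0(NS_XSD, "decimal")),
        rdf_literal(tolower(r$up), datatype = paste0(NS_XSD, "boolean")),
        rdf_literal(tolower(r$initialized), datatype = paste0(NS_XSD, "boolean")),
        rdf_literal(format(r$last_checked, scientific = FALSE, trim = TRUE),
                    datatype = paste0(NS_XSD, "decimal")),
        rdf_iri(r$url)
      )
    )
  })
  registry$endpoint_data <- dplyr::bind_rows(registry$endpoint_data[keep, , drop = FALSE],
                                             records)
  statuses
}

#' @rdname check_availability
#' @export
endpoint_data_graph <- function(registry) registry$endpoint_data

wall_clock_ms <- function() as.numeric(Sys.time()) * 1000

#' Choose the lowest-latency live mirror of a dataset
#'
#' Mirrors marked down are skipped; among live mirrors the one with minimal
#' latency wins, ties broken lexicographically by URL for determinism.
#'
#' @param descriptor A [dataset_descriptor()] (its `endpoint_urls` are the
#'   candidate mirrors, primary first).
#' @param statuses A status tibble from [check_availability()].
#' @return The selected URL.
#' @export
select_mirror <- function(descriptor, statuses) {
  cand <- statuses[statuses$url %in% descriptor$endpoint_urls & statuses$up, , drop = FALSE]
  if (nrow(cand) == 0) {
    stop("no live endpoint for dataset ", descriptor$dataset_id, call. = FALSE)
  }
  cand <- cand[order(cand$latency_ms, cand$url), , drop = FALSE]
  cand$url[1]
}

# resolve the endpoint to use for each dataset of a catalogue:
# live statuses from the registry, lowest-latency mirror per dataset
resolve_endpoints <- function(catalogue, registry, clock = wall_clock_ms) {
  urls <- unique(unlist(lapply(catalogue$descriptors, function(d) d$endpoint_urls)))
  statuses <- check_availability(urls, registry, clock = clock)
  out <- vapply(catalogue$descriptors, function(d) {
    tryCatch(select_mirror(d, statuses), error = function(e) NA_character_)
  }, character(1))
  names(out) <- names(catalogue$descriptors)
  out
}
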