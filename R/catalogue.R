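#' Dataset descriptors and the endpoint catalogue
#'
#' The catalogue (an "autonomous resource discovery index") summarises each
#' federation member as a [dataset_descriptor()]: the distinct classes with a
#' probed example resource and a generalized URI pattern, the distinct
#' predicates with domain/range classes sampled in-graph, and the dataset's
#' endpoint URLs (primary first, mirrors after). [build_catalogue()] derives
#' the two inverted indexes — predicate IRI to datasets and class IRI to
#' datasets — that drive triple-pattern-wise source selection.
#'
#' @param dataset_id Dataset IRI (bare string).
#' @param title Human title; defaults to the IRI local name.
#' @param endpoint_urls Character vector of endpoint URLs, primary first.
#' @param classes Tibble with columns `class_iri`, `label`,
#'   `example_resource`, `uri_regex_pattern`.
#' @param predicates Tibble with columns `predicate_iri`, `label`,
#'   `domain_class`, `range_class`, `example_object`.
#' @param built_at Build timestamp (ISO-8601 string).
#' @param partial Whether probing hit the probe budget and the summary may be
#'   incomplete.
#' @return `dataset_descriptor()` returns a `dataset_descriptor` object.
#' @export
dataset_descriptor <- function(dataset_id, title = iri_local_name(dataset_id),
                               endpoint_urls = character(),
                               classes = empty_class_records(),
                               predicates = empty_predicate_records(),
                               built_at = format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
                               partial = FALSE) {
  stopifnot(length(endpoint_urls) >= 1)
  if (anyDuplicated(predicates$predicate_iri)) {
    stop("duplicate predicate IRIs in descriptor for ", dataset_id, call. = FALSE)
  }
  if (anyDuplicated(classes$class_iri)) {
    stop("duplicate class IRIs in descriptor for ", dataset_id, call. = FALSE)
  }
  structure(
    list(dataset_id = dataset_id, title = title,
         endpoint_urls = endpoint_urls, classes = classes,
         predicates = predicates, built_at = built_at, partial = partial),
    class = "dataset_descriptor"
  )
}

empty_class_records <- function() {
  tibble::tibble(class_iri = character(), label = character(),
                 example_resource = character(), uri_regex_pattern = character())
}

empty_predicate_records <- function() {
  tibble::tibble(predicate_iri = character(), label = character(),
                 domain_class = character(), range_class = character(),
                 example_object = character())
}

#' @export
print.dataset_descriptor <- function(x, ...) {
  cat("<dataset_descriptor> ", x$dataset_id, "\n",
      "  title: ", x$title, "\n",
      "  endpoints: ", paste(x$endpoint_urls, collapse = ", "), "\n",
      "  ", nrow(x$classes), " class(es), ", nrow(x$predicates), " predicate(s)",
      if (x$partial) "  [partial]", "\n", sep = "")
  invisible(x)
}

#' Probe budget for endpoint cataloguing
#'
#' @param max_examples_per_class Example resources recorded per class.
#' @param page_size Maximum distinct classes/predicates retrieved in one
#'   probe; beyond it the descriptor is flagged partial.
#' @param timeout_s Per-request timeout (informational for in-process
#'   endpoints; applied to remote transports).
#' @return A `probe_budget` list.
#' @export
probe_budget <- function(max_examples_per_class = 1L, page_size = 10000L,
                         timeout_s = 60) {
  structure(list(max_examples_per_class = max_examples_per_class,
                 page_size = page_size, timeout_s = timeout_s),
            class = "probe_budget")
}

#' Probe an endpoint and summarise its content
#'
#' Enumerates every distinct class with typed instances and every distinct
#' predicate of the endpoint's graph, records one example resource per class
#' (probe budget permitting) with a URI pattern generalized from it
#' ([derive_uri_pattern()]), and samples each predicate's domain class, range
#' class and an example object. Labels are parsed from the final URI segment.
#' Range classes are taken from `rdf:type` assertions about sampled objects
#' inside the same endpoint (no HTTP dereferencing).
#'
#' @param endpoint A triple tibble, or an [endpoint_registry()] combined with
#'   `url` naming the endpoint to probe.
#' @param dataset_id Dataset IRI for the descriptor.
#' @param endpoint_urls Endpoint URLs to record; defaults to `url` when
#'   probing through a registry.
#' @param url Endpoint URL when `endpoint` is a registry.
#' @param title Dataset title.
#' @param budget A [probe_budget()].
#' @return A [dataset_descriptor()].
#' @export
probe_endpoint <- function(endpoint, dataset_id, endpoint_urls = NULL, url = NULL,
                           title = iri_local_name(dataset_id),
                           budget = probe_budget()) {
  if (inherits(endpoint, "endpoint_registry")) {
    if (is.null(url)) stop("probing a registry requires `url`", call. = FALSE)
    ep <- registry_get(endpoint, url)
    if (is.null(ep)) stop("unknown endpoint: ", url, call. = FALSE)
    if (!ep$up) stop("endpoint unreachable: ", url, call. = FALSE)
    if (is.null(endpoint_urls)) endpoint_urls <- url
    graph <- ep$graph
  } else {
    graph <- endpoint
    if (is.null(endpoint_urls)) {
      stop("probing a bare graph requires `endpoint_urls`", call. = FALSE)
    }
  }
  typed <- graph[graph$p == RDF_TYPE & startsWith(graph$o, "<"), , drop = FALSE]
  class_iris <- sort(unique(iri_value(typed$o)))
  pred_iris <- sort(unique(iri_value(graph$p)))
  partial <- FALSE
  if (length(class_iris) > budget$page_size) {
    class_iris <- class_iris[seq_len(budget$page_size)]
    partial <- TRUE
  }
  if (length(pred_iris) > budget$page_size) {
    pred_iris <- pred_iris[seq_len(budget$page_size)]
    partial <- TRUE
  }
  type_of <- function(node_enc) {
    hit <- typed$o[typed$s == node_enc]
    if (length(hit) == 0) NA_character_ else iri_value(sort(hit)[1])
  }
  classes <- purrr::map_dfr(class_iris, function(ci) {
    inst <- sort(typed$s[typed$o == paste0("<", ci, ">") & startsWith(typed$s, "<")])
    ex <- if (length(inst) >= 1 && budget$max_examples_per_class >= 1) {
      iri_value(inst[1])
    } else NA_character_
    tibble::tibble(
      class_iri = ci, label = iri_local_name(ci),
      example_resource = ex,
      uri_regex_pattern = if (is.na(ex)) NA_character_ else derive_uri_pattern(ex)
    )
  })
  if (nrow(classes) == 0) classes <- empty_class_records()
  predicates <- purrr::map_dfr(pred_iris, function(pi) {
    rows <- graph[graph$p == paste0("<", pi, ">"), , drop = FALSE]
    rows <- rows[order(rows$s, rows$o), , drop = FALSE]
    ex_o <- rows$o[1]
    tibble::tibble(
      predicate_iri = pi, label = iri_local_name(pi),
      domain_class = type_of(rows$s[1]),
      range_class = if (startsWith(ex_o, "<")) type_of(ex_o) else NA_character_,
      example_object = ex_o
    )
  })
  if (nrow(predicates) == 0) predicates <- empty_predicate_records()
  dataset_descriptor(dataset_id, title = title, endpoint_urls = endpoint_urls,
                     classes = classes, predicates = predicates, partial = partial)
}

#' Generalize an example IRI into a URI regex pattern
#'
#' The fixed prefix runs up to and including the last `:`, `/` or `#`
#' delimiter that precedes the local identifier (the `://` of the scheme is
#' ignored); the local identifier is generalized to a wildcard. An IRI with
#' no local segment yields a pattern matching exactly that IRI. The example
#' always matches its own derived pattern.
#'
#' @param example A bare absolute IRI.
#' @return An anchored regex string.
#' @export
#' @examples
#' derive_uri_pattern("http://bio2rdf.org/ec:3.2.1.161")
derive_uri_pattern <- function(example) {
  esc <- function(x) gsub("([^A-Za-z0-9])", "\\\\\\1", x)
  m <- regexpr("^[A-Za-z][A-Za-z0-9+.-]*://", example)
  scheme <- if (m > 0) substr(example, 1L, attr(m, "match.length")) else ""
  rest <- substring(example, nchar(scheme) + 1L)
  pos <- gregexpr("[#:/]", rest)[[1]]
  if (pos[1] == -1 || max(pos) == nchar(rest)) {
    return(paste0("^", esc(example), "$"))
  }
  prefix <- paste0(scheme, substr(rest, 1L, max(pos)))
  paste0("^", esc(prefix), "[^/#]+$")
}

#' @rdname dataset_descriptor
#' @param descriptors A list of `dataset_descriptor` objects.
#' @export
build_catalogue <- function(descriptors) {
  if (inherits(descriptors, "dataset_descriptor")) descriptors <- list(descriptors)
  ids <- vapply(descriptors, function(d) d$dataset_id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate dataset IRI in catalogue: ", ids[duplicated(ids)][1], call. = FALSE)
  }
  names(descriptors) <- ids
  idx <- rebuild_indexes(descriptors)
  structure(list(descriptors = descriptors,
                 predicate_index = idx$predicate_index,
                 class_index = idx$class_index),
            class = "ardi_catalogue")
}

rebuild_indexes <- function(descriptors) {
  predicate_index <- purrr::map_dfr(descriptors, function(d) {
    tibble::tibble(predicate_iri = d$predicates$predicate_iri, dataset_id = d$dataset_id)
  })
  class_index <- purrr::map_dfr(descriptors, function(d) {
    tibble::tibble(class_iri = d$classes$class_iri, dataset_id = d$dataset_id)
  })
  if (nrow(predicate_index) == 0) {
    predicate_index <- tibble::tibble(predicate_iri = character(), dataset_id = character())
  }
  if (nrow(class_index) == 0) {
    class_index <- tibble::tibble(class_iri = character(), dataset_id = character())
  }
  list(predicate_index = predicate_index, class_index = class_index)
}

#' @export
print.ardi_catalogue <- function(x, ...) {
  cat("<ardi_catalogue> ", length(x$descriptors), " dataset(s), ",
      dplyr::n_distinct(x$predicate_index$predicate_iri), " distinct predicate(s), ",
      dplyr::n_distinct(x$class_index$class_iri), " distinct class(es)\n", sep = "")
  invisible(x)
}

#' Look up the datasets carrying a predicate or class
#'
#' @param catalogue An `ardi_catalogue`.
#' @param predicate,class_iri Bare or angle-bracketed IRI.
#' @return Sorted character vector of dataset ids (empty when unknown).
#' @export
predicate_lookup <- function(catalogue, predicate) {
  p <- sub(">$", "", sub("^<", "", predicate))
  sort(unique(catalogue$predicate_index$dataset_id[
    catalogue$predicate_index$predicate_iri == p]))
}

#' @rdname predicate_lookup
#' @export
class_lookup <- function(catalogue, class_iri) {
  ci <- sub(">$", "", sub("^<", "", class_iri))
  sort(unique(catalogue$class_index$dataset_id[
    catalogue$class_index$class_iri == ci]))
}

#' @rdname predicate_lookup
#' @export
catalogue_datasets <- function(catalogue) {
  sort(names(catalogue$descriptors))
}

# --- VoID serialization -----------------------------------------------------

#' Write and read the catalogue as a VoID/Turtle document
#'
#' Each descriptor becomes one `void:Dataset` with multi-valued
#' `void:sparqlEndpoint` (mirrors), top-level `void:class` links, a
#' `void:classPartition` blank node per class (label, `void:exampleResource`,
#' `void:uriRegexPattern`) and a `void:propertyPartition` blank node per
#' predicate (`void:property`, label, `rdfs:domain`/`rdfs:range`, example
#' object under `rdf:value`). Reading reconstructs the descriptors and
#' rebuilds both inverted indexes, so write-then-read is the identity on
#' descriptor content.
#'
#' @param catalogue An `ardi_catalogue` (or a list of descriptors).
#' @param path Output/input file path.
#' @return `write_catalogue()` returns `path` invisibly; `read_catalogue()`
#'   an `ardi_catalogue`.
#' @export
write_catalogue <- function(catalogue, path) {
  descriptors <- if (inherits(catalogue, "ardi_catalogue")) catalogue$descriptors
                 else catalogue
  lit <- function(x) rdf_literal(x)
  lines <- c(
    paste0("@prefix void: <", NS_VOID, "> ."),
    paste0("@prefix rdfs: <", NS_RDFS, "> ."),
    paste0("@prefix rdf: <", NS_RDF, "> ."),
    paste0("@prefix dcterms: <", NS_DCT, "> ."),
    ""
  )
  for (d in descriptors) {
    out <- c(paste0("<", d$dataset_id, "> a void:Dataset ;"),
             paste0("    dcterms:title ", lit(d$title), " ;"),
             paste0("    dcterms:modified ", lit(d$built_at), " ;"),
             paste0("    void:sparqlEndpoint ",
                    paste0("<", d$endpoint_urls, ">", collapse = " , "), " ;"))
    if (d$partial) {
      out <- c(out, paste0("    ", SFED_PARTIAL, " true ;"))
    }
    if (nrow(d$classes) > 0) {
      out <- c(out, paste0("    void:class ",
                           paste0("<", d$classes$class_iri, ">", collapse = " , "), " ;"))
      for (i in seq_len(nrow(d$classes))) {
        cl <- d$classes[i, ]
        part <- c(paste0("void:class <", cl$class_iri, ">"),
                  paste0("rdfs:label ", lit(cl$label)))
        if (!is.na(cl$example_resource)) {
          part <- c(part, paste0("void:exampleResource <", cl$example_resource, ">"))
        }
        if (!is.na(cl$uri_regex_pattern)) {
          part <- c(part, paste0("void:uriRegexPattern ", lit(cl$uri_regex_pattern)))
        }
        out <- c(out, paste0("    void:classPartition [ ",
                             paste(part, collapse = " ; "), " ] ;"))
      }
    }
    for (i in seq_len(nrow(d$predicates))) {
      pr <- d$predicates[i, ]
      part <- c(paste0("void:property <", pr$predicate_iri, ">"),
                paste0("rdfs:label ", lit(pr$label)))
      if (!is.na(pr$domain_class)) part <- c(part, paste0("rdfs:domain <", pr$domain_class, ">"))
      if (!is.na(pr$range_class)) part <- c(part, paste0("rdfs:range <", pr$range_class, ">"))
      if (!is.na(pr$example_object)) part <- c(part, paste0("rdf:value ", pr$example_object))
      out <- c(out, paste0("    void:propertyPartition [ ",
                           paste(part, collapse = " ; "), " ] ;"))
    }
    out[length(out)] <- sub(" ;$", " .", out[length(out)])
    lines <- c(lines, out, "")
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_catalogue
#' @export
read_catalogue <- function(path) {
  st <- parse_turtle(readLines(path, warn = FALSE))
  v <- function(local) paste0("<", NS_VOID, local, ">")
  dct <- function(local) paste0("<", NS_DCT, local, ">")
  objs <- function(s, p) st$o[st$s == s & st$p == p]
  one <- function(s, p) { x <- objs(s, p); if (length(x) == 0) NA_character_ else x[1] }
  lex <- function(x) if (is.na(x)) NA_character_ else literal_parts(x)$lexical
  ds_nodes <- unique(st$s[st$p == RDF_TYPE & st$o == v("Dataset")])
  descriptors <- lapply(ds_nodes, function(node) {
    class_parts <- objs(node, v("classPartition"))
    classes <- purrr::map_dfr(class_parts, function(bn) {
      tibble::tibble(
        class_iri = iri_value(one(bn, v("class"))),
        label = lex(one(bn, RDFS_LABEL)),
        example_resource = {
          e <- one(bn, v("exampleResource"))
          if (is.na(e)) NA_character_ else iri_value(e)
        },
        uri_regex_pattern = lex(one(bn, v("uriRegexPattern")))
      )
    })
    if (length(class_parts) == 0) classes <- empty_class_records()
    prop_parts <- objs(node, v("propertyPartition"))
    predicates <- purrr::map_dfr(prop_parts, function(bn) {
      dom <- one(bn, paste0("<", NS_RDFS, "domain>"))
      rng <- one(bn, paste0("<", NS_RDFS, "range>"))
      tibble::tibble(
        predicate_iri = iri_value(one(bn, v("property"))),
        label = lex(one(bn, RDFS_LABEL)),
        domain_class = if (is.na(dom)) NA_character_ else iri_value(dom),
        range_class = if (is.na(rng)) NA_character_ else iri_value(rng),
        example_object = one(bn, RDF_VALUE)
      )
    })
    if (length(prop_parts) == 0) predicates <- empty_predicate_records()
    partial_o <- one(node, SFED_PARTIAL)
    dataset_descriptor(
      dataset_id = iri_value(node),
      title = lex(one(node, dct("title"))),
      endpoint_urls = iri_value(objs(node, v("sparqlEndpoint"))),
      classes = classes, predicates = predicates,
      built_at = lex(one(node, dct("modified"))),
      partial = !is.na(partial_o) && grepl("true", partial_o, fixed = TRUE)
    )
  })
  build_catalogue(descriptors)
}
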