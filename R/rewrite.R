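#' Exclusive groups of a BGP
#'
#' A triple pattern is exclusive to dataset D when its relevance set is
#' exactly `{D}`; the exclusive group of D within a BGP collects all such
#' patterns. Because no other dataset can contribute to those patterns,
#' the group can be executed at D as one conjunctive sub-query without
#' losing solutions. Groups never span a BGP boundary (and therefore never
#' an OPTIONAL or UNION branch).
#'
#' @param selection A `source_selection` (or its relevance tibble).
#' @return A tibble with one row per (BGP, dataset) exclusive group:
#'   `bgp_id`, `dataset_id`, `ordinals` (list-column of pattern ordinals).
#'   Patterns relevant to zero or several datasets appear in no group.
#' @export
exclusive_groups <- function(selection) {
  rel <- if (inherits(selection, "source_selection")) selection$relevance else selection
  n_rel <- vapply(rel$datasets, length, integer(1))
  excl <- rel[n_rel == 1, , drop = FALSE]
  if (nrow(excl) == 0) {
    return(tibble::tibble(bgp_id = integer(), dataset_id = character(),
                          ordinals = list()))
  }
  excl$dataset_id <- vapply(excl$datasets, `[[`, character(1), 1L)
  excl |>
    dplyr::group_by(.data$bgp_id, .data$dataset_id) |>
    dplyr::summarise(ordinals = list(sort(.data$ordinal)), .groups = "drop") |>
    dplyr::arrange(.data$bgp_id, vapply(.data$ordinals, min, integer(1)))
}

#' Rewrite a query into SPARQL 1.1 SERVICE form
#'
#' The source-selection result turns each BGP of the query into federated
#' form: every exclusive group becomes one SERVICE block against its
#' dataset's chosen endpoint; every remaining pattern becomes a UNION over
#' one SERVICE block per relevant dataset (a single-dataset non-grouped
#' pattern is a lone SERVICE block). Blocks are emitted in ascending order
#' of the smallest pattern ordinal they contain. OPTIONAL/UNION structure,
#' FILTERs and solution modifiers of the original query are preserved; a
#' filter whose variables are all bound inside exactly one SERVICE block is
#' pushed into that block, otherwise it stays outside. Patterns with an
#' empty relevance set become blocks with no solutions (`FILTER(false)`)
#' under a warning, or an error under `strict = TRUE`.
#'
#' @param q A `sparql_query` or SPARQL text.
#' @param selection The `source_selection` for `q`.
#' @param catalogue The catalogue used for selection (endpoint mirrors).
#' @param registry Registry used to pick the lowest-latency live mirror.
#' @param group Build exclusive groups (`FALSE` emits one SERVICE — or
#'   UNION of SERVICEs — per pattern).
#' @param strict Fail on empty relevance sets instead of emitting empty
#'   blocks.
#' @return An object of class `rewritten_query`: list with `text`
#'   (SPARQL 1.1), `query` (the rewritten `sparql_query`), `blocks`
#'   (tibble: `bgp_id`, `kind` = exclusive/union/empty, `dataset_id`,
#'   `endpoint`, `n_patterns`, `ordinals`), and `endpoint_of`.
#' @export
rewrite_query <- function(q, selection, catalogue, registry,
                          group = TRUE, strict = FALSE) {
  if (is.character(q)) q <- parse_query(q)
  rel <- selection$relevance
  endpoint_of <- selection$endpoint_of
  needed <- unique(unlist(rel$datasets))
  missing_ep <- needed[is.na(endpoint_of[needed])]
  if (length(missing_ep) > 0) {
    stop("no live endpoint for dataset(s): ", paste(missing_ep, collapse = ", "),
         call. = FALSE)
  }
  blocks <- list()
  note_block <- function(bgp_id, kind, dataset_id, endpoint, ordinals) {
    blocks[[length(blocks) + 1L]] <<- tibble::tibble(
      bgp_id = bgp_id, kind = kind, dataset_id = dataset_id,
      endpoint = endpoint, n_patterns = length(ordinals), ordinals = list(ordinals))
  }
  eg <- if (group) exclusive_groups(selection) else
    tibble::tibble(bgp_id = integer(), dataset_id = character(), ordinals = list())

  rewrite_bgp <- function(node) {
    bid <- node$id
    rel_b <- rel[rel$bgp_id == bid, , drop = FALSE]
    rel_of <- stats::setNames(rel_b$datasets, rel_b$ordinal)
    eg_b <- eg[eg$bgp_id == bid, , drop = FALSE]
    grouped <- unlist(eg_b$ordinals)
    parts <- list()   # one element per emitted block, with its min ordinal
    add_part <- function(min_ord, part) {
      parts[[length(parts) + 1L]] <<- list(min_ord = min_ord, node = part)
    }
    svc_block <- function(ds, ordinals) {
      sub <- node$patterns[node$patterns$ordinal %in% ordinals, , drop = FALSE]
      list(type = "service", endpoint = rdf_iri(endpoint_of[[ds]]), silent = FALSE,
           inner = list(type = "bgp", id = bid,
                        patterns = sub))
    }
    for (i in seq_len(nrow(eg_b))) {
      ords <- eg_b$ordinals[[i]]
      ds <- eg_b$dataset_id[i]
      add_part(min(ords), svc_block(ds, ords))
      note_block(bid, "exclusive", ds, endpoint_of[[ds]], ords)
    }
    for (ord in setdiff(node$patterns$ordinal, grouped)) {
      dss <- rel_of[[as.character(ord)]]
      if (length(dss) == 0) {
        if (strict) {
          stop("triple pattern ", bid, "/", ord,
               " has an empty relevance set (strict mode)", call. = FALSE)
        }
        warning("triple pattern ", bid, "/", ord,
                " has an empty relevance set; emitting empty block", call. = FALSE)
        add_part(ord, list(type = "filter",
                           expr = list(type = "term",
                                       term = rdf_literal("false", datatype = paste0(NS_XSD, "boolean"))),
                           inner = list(type = "unit")))
        note_block(bid, "empty", NA_character_, NA_character_, ord)
      } else if (length(dss) == 1) {
        add_part(ord, svc_block(dss, ord))
        note_block(bid, if (group) "exclusive" else "service", dss,
                   endpoint_of[[dss]], ord)
      } else {
        branches <- lapply(sort(dss), function(ds) svc_block(ds, ord))
        for (ds in sort(dss)) note_block(bid, "union", ds, endpoint_of[[ds]], ord)
        add_part(ord, list(type = "union", parts = branches))
      }
    }
    parts <- parts[order(vapply(parts, function(p) min(p$min_ord), numeric(1)))]
    nodes <- lapply(parts, `[[`, "node")
    if (length(nodes) == 0) list(type = "unit")
    else if (length(nodes) == 1) nodes[[1]]
    else list(type = "join", parts = nodes)
  }

  walk <- function(n) {
    switch(n$type,
      bgp = rewrite_bgp(n),
      join = { n$parts <- lapply(n$parts, walk); n },
      union = { n$parts <- lapply(n$parts, walk); n },
      optional = { n$left <- walk(n$left); n$right <- walk(n$right); n },
      filter = {
        n$inner <- walk(n$inner)
        push_filter(n)
      },
      service = n,
      unit = n,
      stop("unknown algebra node type: ", n$type)
    )
  }
  new_q <- q
  new_q$algebra <- walk(q$algebra)
  new_q$text <- NULL
  text <- serialize_query(new_q)
  new_q$text <- text
  blocks_tbl <- if (length(blocks)) dplyr::bind_rows(blocks) else
    tibble::tibble(bgp_id = integer(), kind = character(), dataset_id = character(),
                   endpoint = character(), n_patterns = integer(), ordinals = list())
  structure(list(text = text, query = new_q, blocks = blocks_tbl,
                 endpoint_of = endpoint_of[needed]),
            class = "rewritten_query")
}

# push a FILTER into the single SERVICE block binding all its variables;
# otherwise leave it at the original level
push_filter <- function(fnode) {
  vars <- expr_variables(fnode$expr)
  inner <- fnode$inner
  parts <- if (inner$type == "join") inner$parts else list(inner)
  binds_all <- vapply(parts, function(p) {
    p$type == "service" && all(vars %in% node_variables(p$inner))
  }, logical(1))
  if (length(vars) > 0 && sum(binds_all) == 1) {
    i <- which(binds_all)
    svc <- parts[[i]]
    svc$inner <- list(type = "filter", expr = fnode$expr, inner = svc$inner)
    parts[[i]] <- svc
    if (inner$type == "join") {
      inner$parts <- parts
      return(inner)
    }
    return(parts[[1]])
  }
  fnode
}

#' @export
print.rewritten_query <- function(x, ...) {
  cat("<rewritten_query> ", nrow(x$blocks), " block(s) over ",
      dplyr::n_distinct(x$blocks$dataset_id, na.rm = TRUE), " dataset(s)\n",
      sep = "")
  cat(x$text, "\n")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.rewritten_query <- function(x, ...) x$blocks
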