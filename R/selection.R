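#' Triple-pattern-wise source selection
#'
#' Implements the hybrid two-step selection: for every triple pattern of the
#' query, (1) candidate datasets come from the catalogue — all datasets when
#' the predicate is a variable, otherwise the predicate index — and (2) when
#' the pattern's subject or object is bound, one SPARQL ASK carrying the
#' pattern is sent to each candidate and candidates answering false are
#' removed. The result is the per-pattern relevance sets together with a
#' report accounting the total triple-pattern-wise sources selected
#' (TTPWSS: the sum of relevance-set sizes), the number of ASK requests
#' issued (#AR), and the source selection time (SST), split into catalogue
#' and ASK components.
#'
#' Candidates whose endpoints are all down are dropped before pruning when
#' `availability_filter` is on (the preemptive availability test). ASK
#' transport failures follow `ask_policy`: `"drop"` removes the dataset and
#' records the event, `"abort"` raises. Patterns whose final relevance set
#' is empty are retained with a warning — downstream they become
#' empty-solution blocks.
#'
#' @param q A `sparql_query` or SPARQL text.
#' @param catalogue An [build_catalogue()] result.
#' @param registry An [endpoint_registry()] supplying the ASK capability.
#' @param prune Run the ASK pruning step (disable to obtain index-only
#'   selection).
#' @param availability_filter Exclude datasets with no live endpoint before
#'   ASK pruning.
#' @param ask_policy `"drop"` or `"abort"` on ASK transport failure.
#' @return An object of class `source_selection`: list with `relevance`
#'   (tibble `bgp_id`, `ordinal`, `s`, `p`, `o`, `datasets` list-column),
#'   `report` (see [glance.source_selection()]) and `endpoint_of` (dataset
#'   to endpoint URL map used for the ASKs).
#' @export
select_sources <- function(q, catalogue, registry,
                           prune = TRUE, availability_filter = TRUE,
                           ask_policy = c("drop", "abort")) {
  ask_policy <- match.arg(ask_policy)
  if (is.character(q)) q <- parse_query(q)
  if (length(catalogue$descriptors) == 0) {
    stop("source selection requires a non-empty catalogue", call. = FALSE)
  }
  pats <- query_patterns(q)
  all_ds <- sort(names(catalogue$descriptors))
  t0 <- proc.time()[["elapsed"]]
  # step 1: catalogue lookup
  candidates <- lapply(seq_len(nrow(pats)), function(i) {
    p <- pats$p[i]
    if (is_varlike_term(p)) all_ds else predicate_lookup(catalogue, p)
  })
  endpoint_of <- resolve_endpoints(catalogue, registry)
  if (availability_filter) {
    live <- names(endpoint_of)[!is.na(endpoint_of)]
    candidates <- lapply(candidates, intersect, y = live)
  }
  t1 <- proc.time()[["elapsed"]]
  # step 2: ASK pruning for patterns with bound subject or object
  ask_requests <- 0L
  before <- vapply(candidates, length, integer(1))
  pruned <- integer(nrow(pats))
  final <- candidates
  if (prune) {
    for (i in seq_len(nrow(pats))) {
      s <- pats$s[i]; p <- pats$p[i]; o <- pats$o[i]
      if (!term_is_bound(s) && !term_is_bound(o)) next
      keep <- character(0)
      for (ds in candidates[[i]]) {
        url <- endpoint_of[[ds]]
        ask_requests <- ask_requests + 1L
        ans <- tryCatch(endpoint_ask(registry, url, s, p, o), error = function(e) e)
        if (inherits(ans, "error")) {
          if (ask_policy == "abort") {
            stop("ASK failed against ", ds, " (", url, "): ",
                 conditionMessage(ans), call. = FALSE)
          }
          next
        }
        if (isTRUE(as.logical(ans))) keep <- c(keep, ds)
      }
      pruned[i] <- length(candidates[[i]]) - length(keep)
      final[[i]] <- keep
    }
  }
  t2 <- proc.time()[["elapsed"]]
  relevance <- dplyr::mutate(pats, datasets = final)
  n_empty <- sum(vapply(final, length, integer(1)) == 0)
  if (n_empty > 0) {
    warning(n_empty, " triple pattern(s) have an empty relevance set; ",
            "they will produce empty solution blocks", call. = FALSE)
  }
  report <- list(
    ttpwss = sum(vapply(final, length, integer(1))),
    ask_requests = ask_requests,
    selection_time_ms = (t2 - t0) * 1000,
    index_time_ms = (t1 - t0) * 1000,
    ask_time_ms = (t2 - t1) * 1000,
    per_pattern_before = before,
    per_pattern_pruned = pruned
  )
  structure(list(relevance = relevance, report = report, endpoint_of = endpoint_of),
            class = "source_selection")
}

#' Total triple-pattern-wise sources selected
#'
#' The sum over the query's triple patterns of the size of each pattern's
#' relevance set.
#'
#' @param x A `source_selection`, or its relevance tibble.
#' @return Integer.
#' @export
ttpwss <- function(x) {
  rel <- if (inherits(x, "source_selection")) x$relevance else x
  sum(vapply(rel$datasets, length, integer(1)))
}

#' ASK budget of index-free source selection
#'
#' An index-free federation engine with a cold cache must send one ASK per
#' (dataset, triple pattern) pair, so its request count is the product of
#' the number of datasets and the number of triple patterns — the baseline
#' against which the catalogue-assisted selection is compared.
#'
#' @param q A `sparql_query`, SPARQL text, or directly a triple-pattern
#'   count.
#' @param n_datasets Number of federation members.
#' @return Integer number of ASK requests.
#' @export
#' @examples
#' index_free_ask_count("SELECT * WHERE { ?s ?p ?o . ?s ?q ?v }", 10)
index_free_ask_count <- function(q, n_datasets) {
  stopifnot(n_datasets >= 0)
  tp <- if (is.numeric(q)) as.integer(q) else {
    if (is.character(q)) q <- parse_query(q)
    nrow(query_patterns(q))
  }
  as.integer(n_datasets) * tp
}

#' @export
print.source_selection <- function(x, ...) {
  cat("<source_selection> TTPWSS ", x$report$ttpwss,
      ", #AR ", x$report$ask_requests,
      sprintf(", SST %.1f ms\n", x$report$selection_time_ms), sep = "")
  sets <- vapply(x$relevance$datasets, function(d) paste(d, collapse = ", "), character(1))
  for (i in seq_len(nrow(x$relevance))) {
    cat(sprintf("  [%d/%d] %s %s %s -> {%s}\n",
                x$relevance$bgp_id[i], x$relevance$ordinal[i],
                x$relevance$s[i], x$relevance$p[i], x$relevance$o[i], sets[i]))
  }
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.source_selection <- function(x, ...) {
  dplyr::mutate(x$relevance,
                n_candidates = x$report$per_pattern_before,
                n_pruned = x$report$per_pattern_pruned,
                n_relevant = vapply(x$relevance$datasets, length, integer(1)))
}

#' Selection report summary
#'
#' @param x A `source_selection`.
#' @param ... Unused.
#' @return One-row tibble with `ttpwss`, `ask_requests`,
#'   `selection_time_ms`, `index_time_ms`, `ask_time_ms`.
#' @exportS3Method generics::glance
glance.source_selection <- function(x, ...) {
  tibble::tibble(
    ttpwss = x$report$ttpwss,
    ask_requests = x$report$ask_requests,
    selection_time_ms = x$report$selection_time_ms,
    index_time_ms = x$report$index_time_ms,
    ask_time_ms = x$report$ask_time_ms
  )
}
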