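#' Query characterization metrics
#'
#' Computes the structural features used to characterise federated benchmark
#' queries: number of BGPs, number of triple patterns (#TP), total vertices
#' (TVs — distinct terms occurring in any subject/predicate/object position,
#' query-wide), join vertices (JVs — distinct terms occurring in two or more
#' triple patterns of the same BGP), the ratio R = JVs/TVs, the mean join
#' vertex degree D (a join vertex's degree is the number of triple patterns
#' of the same BGP containing it; a vertex joining in several BGPs counts
#' once with its maximum per-BGP degree), and the SPARQL clauses used.
#'
#' Variables are compared by name, IRIs and literals by string; blank nodes
#' behave as variables. By default every position — including the predicate —
#' can make a term a join vertex; `join_positions = "so"` restricts joins to
#' subject/object occurrences (common predicates such as `rdf:type` then
#' never count as join vertices).
#'
#' `ratio` is reported at full precision; [truncate3()] reproduces the
#' truncate-to-3-decimals display convention of published benchmark tables
#' (2/7 prints as 0.285, not 0.286).
#'
#' @param q A `sparql_query`, or SPARQL text (parsed on the fly).
#' @param join_positions `"spo"` (default) or `"so"`.
#' @return A `query_features` object; `tidy()` turns it into a one-row
#'   tibble with columns `bgp_count`, `tp_count`, `total_vertices`,
#'   `join_vertices`, `ratio`, `mean_join_degree`, `clauses`.
#' @export
#' @examples
#' q <- parse_query("SELECT * WHERE { ?s ?p ?o }")
#' compute_features(q)
compute_features <- function(q, join_positions = c("spo", "so")) {
  join_positions <- match.arg(join_positions)
  if (is.character(q)) q <- parse_query(q)
  pats <- query_patterns(q)
  if (nrow(pats) == 0) {
    return(structure(
      list(bgp_count = 0L, tp_count = 0L, total_vertices = 0L,
           join_vertices = 0L, ratio = 0, mean_join_degree = 0,
           clauses = character(0), join_vertex_names = character(0)),
      class = "query_features"))
  }
  long <- tidyr::pivot_longer(
    dplyr::mutate(pats, pattern_key = paste0(bgp_id, "/", ordinal)),
    cols = c("s", "p", "o"), names_to = "position", values_to = "term"
  )
  if (join_positions == "so") {
    join_long <- dplyr::filter(long, position != "p")
  } else {
    join_long <- long
  }
  # canonical vertex identity: variables and blanks by binding name, rest verbatim
  canon <- function(x) ifelse(is_varlike_term(x), paste0("?", var_name(x)), x)
  long$vertex <- canon(long$term)
  join_long$vertex <- canon(join_long$term)
  total_vertices <- dplyr::n_distinct(long$vertex)
  # degree of vertex v in BGP b: number of patterns of b containing v
  deg <- join_long |>
    dplyr::distinct(.data$bgp_id, .data$pattern_key, .data$vertex) |>
    dplyr::count(.data$bgp_id, .data$vertex, name = "degree")
  deg2 <- dplyr::filter(deg, .data$degree >= 2)
  jv <- if (nrow(deg2) == 0) deg2[, c("vertex", "degree")] else {
    deg2 |>
      dplyr::group_by(.data$vertex) |>
      dplyr::summarise(degree = max(.data$degree), .groups = "drop")
  }
  clauses <- character(0)
  found <- algebra_clauses(q$algebra)
  if (q$distinct) clauses <- c(clauses, "DISTINCT")
  clauses <- c(clauses, found)
  if (!is.na(q$limit)) clauses <- c(clauses, "LIMIT")
  if (nrow(q$order_by) > 0) clauses <- c(clauses, "ORDER BY")
  structure(
    list(
      bgp_count = dplyr::n_distinct(pats$bgp_id),
      tp_count = nrow(pats),
      total_vertices = total_vertices,
      join_vertices = nrow(jv),
      ratio = if (total_vertices > 0) nrow(jv) / total_vertices else 0,
      mean_join_degree = if (nrow(jv) > 0) mean(jv$degree) else 0,
      clauses = unique(clauses),
      join_vertex_names = sort(jv$vertex)
    ),
    class = "query_features"
  )
}

algebra_clauses <- function(node) {
  out <- character(0)
  walk <- function(n) {
    switch(n$type,
      optional = { out <<- c(out, "OPTIONAL"); walk(n$left); walk(n$right) },
      union = { out <<- c(out, "UNION"); lapply(n$parts, walk) },
      filter = {
        out <<- c(out, "FILTER")
        if (expr_uses_regex(n$expr)) out <<- c(out, "REGEX")
        walk(n$inner)
      },
      join = lapply(n$parts, walk),
      service = walk(n$inner),
      NULL
    )
    invisible(NULL)
  }
  walk(node)
  unique(out)
}

expr_uses_regex <- function(expr) {
  switch(expr$type,
    call = expr$fn == "regex" || any(vapply(expr$args, expr_uses_regex, logical(1))),
    op = any(vapply(expr$args, expr_uses_regex, logical(1))),
    FALSE
  )
}

#' Truncate to three decimals
#'
#' Display convention for join-vertex ratios in benchmark tables: values are
#' cut, not rounded (2/7 = 0.2857... displays as 0.285).
#'
#' @param x Numeric vector.
#' @return `x` truncated towards zero at the third decimal.
#' @export
truncate3 <- function(x) trunc(x * 1000) / 1000

#' @export
print.query_features <- function(x, ...) {
  cat("<query_features>\n")
  cat(sprintf("  #BGPs %d  #TP %d  TVs %d  JVs %d  R %.4f (%.3f)  D %.3f\n",
              x$bgp_count, x$tp_count, x$total_vertices, x$join_vertices,
              x$ratio, truncate3(x$ratio), x$mean_join_degree))
  cat("  clauses:", if (length(x$clauses)) paste(x$clauses, collapse = ", ") else "none", "\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @exportS3Method generics::tidy
tidy.query_features <- function(x, truncate = FALSE, ...) {
  tibble::tibble(
    bgp_count = x$bgp_count, tp_count = x$tp_count,
    total_vertices = x$total_vertices, join_vertices = x$join_vertices,
    ratio = if (truncate) truncate3(x$ratio) else x$ratio,
    mean_join_degree = x$mean_join_degree,
    clauses = paste(x$clauses, collapse = ",")
  )
}

#' Feature statistics of the 20-query life-science federation benchmark
#'
#' The published per-query feature table for the 10 simple and 10 complex
#' federated benchmark queries over the ten-dataset life-science federation:
#' query id and type, #BGPs, #TP, total and join vertices, ratio (as printed,
#' truncated to three decimals), mean join degree and SPARQL clauses. These
#' are recorded inputs, not values computed by this package; the `#TP` column
#' drives the index-free source-selection baseline (see
#' [index_free_ask_count()]).
#'
#' @return A 20-row tibble.
#' @export
benchmark_query_features <- function() {
  path <- system.file("extdata", "benchmark_queries.csv", package = "sparqlfed",
                      mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE)
}
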