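test_that("execution instruments one provenance record per SERVICE invocation", {
  fed <- we_fed()
  sel <- select_sources(worked_example_query(), fed$catalogue, fed$registry)
  rw <- rewrite_query(worked_example_query(), sel, fed$catalogue, fed$registry)
  res <- execute_query(rw, fed$registry)
  prov <- res$provenance
  expect_equal(nrow(prov$services), 4)
  expect_true(all(prov$services$status == "ok"))
  expect_true(all(prov$services$end_ms >= prov$services$start_ms))
  expect_equal(prov$services$elapsed_ms,
               prov$services$end_ms - prov$services$start_ms)
  expect_gte(prov$total_elapsed_ms, max(prov$services$elapsed_ms))
  # federated result equals the merged-graph evaluation
  merged <- merge_graphs(fed$graphs)
  expect_true(same_solutions(res$results, run_sparql(worked_example_query(), merged)))
  expect_gte(nrow(res$results), 1)
})

test_that("per-service result counts equal independent per-block evaluation", {
  fed <- we_fed()
  sel <- select_sources(worked_example_query(), fed$catalogue, fed$registry)
  rw <- rewrite_query(worked_example_query(), sel, fed$catalogue, fed$registry)
  res <- execute_query(rw, fed$registry)
  # walk the rewritten algebra collecting the service nodes in evaluation order
  svc_nodes <- list()
  walk <- function(n) {
    if (n$type == "service") svc_nodes[[length(svc_nodes) + 1L]] <<- n
    for (k in switch(n$type, join = , union = n$parts,
                     optional = list(n$left, n$right),
                     filter = , service = list(n$inner), list())) walk(k)
  }
  walk(rw$query$algebra)
  expect_equal(length(svc_nodes), nrow(res$provenance$services))
  for (i in seq_along(svc_nodes)) {
    url <- iri_value(svc_nodes[[i]]$endpoint)
    alone <- sparqlfed:::endpoint_evaluate(fed$registry, url, svc_nodes[[i]]$inner)
    rec <- res$provenance$services[res$provenance$services$endpoint == url, ]
    expect_true(nrow(alone) %in% rec$result_count)
  }
})

test_that("a federation of empty graphs returns nothing with zero counts", {
  reg <- endpoint_registry()
  register_endpoint(reg, "http://a.example.org/sparql", rdf_graph(), latency_ms = 1)
  register_endpoint(reg, "http://b.example.org/sparql", rdf_graph(), latency_ms = 2)
  q <- "SELECT * WHERE {
    SERVICE <http://a.example.org/sparql> { ?s ?p ?o }
    SERVICE <http://b.example.org/sparql> { ?s ?p2 ?o2 } }"
  res <- execute_query(q, reg)
  expect_equal(nrow(res$results), 0)
  expect_equal(res$provenance$services$result_count, c(0L, 0L))
})

test_that("provenance retention: immediate fetch, 10-minute expiry, session eviction", {
  fed <- we_fed()
  sel <- select_sources(worked_example_query(), fed$catalogue, fed$registry)
  rw <- rewrite_query(worked_example_query(), sel, fed$catalogue, fed$registry)
  t <- 1e12
  clock <- function() t
  res1 <- execute_query(rw, fed$registry, session = "alice", clock = clock)
  id1 <- res1$provenance$query_id
  expect_equal(get_provenance(id1, clock = clock)$query_id, id1)
  expect_equal(res1$provenance$retention_deadline,
               res1$provenance$created_at + 10 * 60 * 1000)
  # within the window
  t <- t + 9 * 60 * 1000
  expect_equal(get_provenance(id1, clock = clock)$query_id, id1)
  # past the window
  t <- t + 2 * 60 * 1000
  expect_error(get_provenance(id1, clock = clock),
               class = "sparqlfed_provenance_not_found")
  # eviction on the same session's next query; other sessions unaffected
  t <- 2e12
  ra <- execute_query(rw, fed$registry, session = "alice", clock = clock)
  rb <- execute_query(rw, fed$registry, session = "bob", clock = clock)
  ra2 <- execute_query(rw, fed$registry, session = "alice", clock = clock)
  expect_error(get_provenance(ra$provenance$query_id, clock = clock),
               class = "sparqlfed_provenance_not_found")
  expect_equal(get_provenance(rb$provenance$query_id, clock = clock)$session, "bob")
  expect_equal(get_provenance(ra2$provenance$query_id, clock = clock)$session, "alice")
})

test_that("killing one endpoint yields one down record and partial results", {
  fed <- worked_example_fixture()
  sel <- select_sources(worked_example_query(), fed$catalogue, fed$registry)
  rw <- rewrite_query(worked_example_query(), sel, fed$catalogue, fed$registry)
  chebi_url <- fed$endpoints[[fed$dataset_ids[["chebi"]]]]
  set_endpoint_up(fed$registry, chebi_url, FALSE)
  res <- execute_query(rw, fed$registry)
  expect_equal(sum(res$provenance$services$status == "down"), 1)
  expect_true(all(!is.na(res$provenance$services$message[
    res$provenance$services$status == "down"])))
  # partial results: the KEGG title branch still answers
  expect_gte(nrow(res$results), 1)
  expect_error(execute_query(rw, fed$registry, strict = TRUE), "SERVICE")
})

test_that("availability checks update the queryable EndpointData graph", {
  reg <- endpoint_registry()
  register_endpoint(reg, "http://u1.example.org/sparql", rdf_graph(), latency_ms = 50)
  register_endpoint(reg, "http://u2.example.org/sparql", rdf_graph(), latency_ms = 10)
  t <- 5e11
  st <- check_availability(registry_urls(reg), reg, clock = function() t)
  expect_true(all(st$up))
  expect_equal(st$latency_ms[st$url == "http://u2.example.org/sparql"], 10)
  # unresolvable URL -> down record
  st2 <- check_availability("http://ghost.example.org/sparql", reg,
                            clock = function() t + 1)
  expect_false(st2$up)
  expect_true(is.na(st2$latency_ms))
  # SPARQL readback over EndpointData returns exactly what was recorded
  out <- run_sparql(paste0(
    "SELECT ?ep ?lat ?up WHERE { ?ep <", sparqlfed:::SFED_NS, "latency> ?lat . ",
    "?ep <", sparqlfed:::SFED_NS, "up> ?up }"), endpoint_data_graph(reg))
  expect_equal(nrow(out), 3)
  lat_of <- function(u) out$lat[out$ep == rdf_iri(u)]
  expect_equal(lat_of("http://u1.example.org/sparql"),
               rdf_literal("50", datatype = paste0(sparqlfed:::NS_XSD, "decimal")))
  expect_equal(out$up[out$ep == rdf_iri("http://ghost.example.org/sparql")],
               rdf_literal("false", datatype = paste0(sparqlfed:::NS_XSD, "boolean")))
  # re-checking replaces the old cycle's records (no duplicates)
  check_availability(registry_urls(reg), reg, clock = function() t + 2)
  out2 <- run_sparql(paste0(
    "SELECT ?ep WHERE { ?ep <", sparqlfed:::SFED_NS, "latency> ?lat }"),
    endpoint_data_graph(reg))
  expect_equal(sum(out2$ep == rdf_iri("http://u1.example.org/sparql")), 1)
})

test_that("mirror selection takes the lowest-latency live endpoint", {
  d <- dataset_descriptor("http://x/ds", endpoint_urls = c("http://u1", "http://u2"))
  st <- tibble::tibble(url = c("http://u1", "http://u2"),
                       latency_ms = c(50, 10), up = c(TRUE, TRUE),
                       initialized = TRUE, last_checked = 0)
  expect_equal(select_mirror(d, st), "http://u2")
  st$up[st$url == "http://u2"] <- FALSE
  st$latency_ms[st$url == "http://u2"] <- NA
  expect_equal(select_mirror(d, st), "http://u1")
  st$up <- FALSE
  expect_error(select_mirror(d, st), "no live endpoint")
  # deterministic lexicographic tie-break
  st2 <- tibble::tibble(url = c("http://b", "http://a"), latency_ms = c(7, 7),
                        up = TRUE, initialized = TRUE, last_checked = 0)
  d2 <- dataset_descriptor("http://x/ds2", endpoint_urls = c("http://b", "http://a"))
  expect_equal(select_mirror(d2, st2), "http://a")
  # single live URL: itself
  d3 <- dataset_descriptor("http://x/ds3", endpoint_urls = "http://only")
  st3 <- tibble::tibble(url = "http://only", latency_ms = 3, up = TRUE,
                        initialized = TRUE, last_checked = 0)
  expect_equal(select_mirror(d3, st3), "http://only")
})
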