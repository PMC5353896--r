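test_that("generation is deterministic under the seed", {
  cfg <- topology_config(n_datasets = 4, seed = 123)
  f1 <- generate_federation(cfg)
  f2 <- generate_federation(topology_config(n_datasets = 4, seed = 123))
  for (nm in names(f1$graphs)) {
    a <- withr::local_tempfile(); b <- withr::local_tempfile()
    write_graph(f1$graphs[[nm]], a)
    write_graph(f2$graphs[[nm]], b)
    expect_identical(readLines(a), readLines(b), info = nm)
  }
  f3 <- generate_federation(topology_config(n_datasets = 4, seed = 124))
  expect_false(identical(f1$graphs, f3$graphs))
})

test_that("the stated topology holds: exclusive, shared, linked, overlapping", {
  fed <- gen_fed()
  cfg <- fed$config
  # exclusive predicate of dataset 3 is relevant only there
  d3 <- names(fed$graphs)[3]
  excl <- paste0("<http://bio2rdf.org/ns/", d3, "#p1>")
  expect_equal(fed$truth("?x", excl, "?y"), unname(fed$dataset_ids[[d3]]))
  # shared predicates occur in every dataset
  for (sp in cfg$shared_predicates) {
    expect_setequal(fed$truth("?x", rdf_iri(sp), "?y"), unname(fed$dataset_ids))
  }
  # cross-links: the link predicate matches in its source dataset
  for (i in seq_len(nrow(cfg$cross_links))) {
    cl <- cfg$cross_links[i, ]
    expect_true(fed$dataset_ids[[cl$source]] %in%
                  fed$truth("?x", rdf_iri(cl$predicate), "?y"))
  }
  # literal overlap: some literal appears under both predicates
  ov <- cfg$literal_overlaps[1, ]
  ga <- fed$graphs[[ov$dataset_a]]
  gb <- fed$graphs[[ov$dataset_b]]
  la <- ga$o[ga$p == rdf_iri(ov$predicate_a)]
  lb <- gb$o[gb$p == rdf_iri(ov$predicate_b)]
  expect_gt(length(intersect(la, lb)), 0)
  # no identical triple is served by two datasets (multiset-exact federation)
  all_triples <- unlist(lapply(fed$graphs, function(g) paste(g$s, g$p, g$o)))
  expect_false(any(duplicated(all_triples)))
})

test_that("truth agrees with per-graph evaluation on 500 seeded probe patterns", {
  fed <- gen_fed()
  merged <- merge_graphs(fed$graphs)
  set.seed(1234)
  for (i in 1:500) {
    tr <- merged[sample(nrow(merged), 1), ]
    s <- if (runif(1) < 0.5) "?s" else tr$s
    p <- if (runif(1) < 0.3) "?p" else tr$p
    o <- if (runif(1) < 0.5) "?o" else tr$o
    expect_equal(fed$truth(s, p, o), oracle_relevance(fed, s, p, o),
                 info = paste(s, p, o))
  }
})

test_that("catalogue descriptors equal a fresh probe of each graph", {
  fed <- gen_fed()
  for (nm in names(fed$graphs)) {
    id <- fed$dataset_ids[[nm]]
    d <- fed$catalogue$descriptors[[id]]
    fresh <- probe_endpoint(fed$graphs[[nm]], dataset_id = id,
                            endpoint_urls = d$endpoint_urls, title = d$title)
    expect_equal(as.data.frame(fresh$classes), as.data.frame(d$classes), info = nm)
    expect_equal(as.data.frame(fresh$predicates), as.data.frame(d$predicates), info = nm)
  }
})

test_that("deregistering a dataset removes it from all truth sets", {
  fed <- generate_federation(topology_config(n_datasets = 5, seed = 9))
  victim <- names(fed$graphs)[2]
  vid <- fed$dataset_ids[[victim]]
  before <- fed$truth("?x", RDF_TYPE, "?y")
  expect_true(vid %in% before)
  deregister_endpoint(fed$registry, fed$endpoints[[vid]])
  after <- fed$truth("?x", RDF_TYPE, "?y")
  expect_false(vid %in% after)
  expect_setequal(after, setdiff(before, vid))
})

test_that("invalid topologies are rejected", {
  expect_error(topology_config(
    n_datasets = 3,
    literal_overlaps = tibble::tibble(dataset_a = "drugbank", predicate_a = "http://x/a",
                                      dataset_b = "nosuch", predicate_b = "http://x/b")),
    "unknown dataset")
  expect_error(topology_config(
    n_datasets = 2,
    cross_links = tibble::tibble(source = "ghost", target = "kegg",
                                 predicate = "http://x/l")),
    "unknown dataset")
})

test_that("the worked-example fixture satisfies its construction contract", {
  fed <- we_fed()
  expect_length(fed$graphs, 10)
  expect_setequal(names(fed$graphs),
                  c("drugbank", "kegg", "chebi", "sider", "diseasome", "dailymed",
                    "linkedct", "medicare", "affymetrix", "tcga"))
  # ASK {?keggDrug rdf:type kegg:Drug} true only on the KEGG graph
  hits <- names(fed$graphs)[vapply(fed$graphs, function(g) {
    graph_ask(g, "?keggDrug", RDF_TYPE, "<http://bio2rdf.org/ns/kegg#Drug>")
  }, logical(1))]
  expect_equal(hits, "kegg")
  # rdf:type occurs in all ten graphs
  expect_true(all(vapply(fed$graphs, function(g) any(g$p == RDF_TYPE), logical(1))))
  # the merged graph yields at least one solution for the five-pattern query
  expect_gte(nrow(run_sparql(worked_example_query(), merge_graphs(fed$graphs))), 1)
})
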