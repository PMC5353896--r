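test_that("probing a KEGG-like graph records its classes, predicates and examples", {
  enz <- "<http://bio2rdf.org/ec:3.2.1.161>"
  g <- rdf_graph(
    s = c(enz, enz, enz, enz),
    p = c(RDF_TYPE,
          "<http://bio2rdf.org/ns/bio2rdf#synonym>",
          "<http://bio2rdf.org/ns/kegg#xSubstrate>",
          "<http://bio2rdf.org/ns/kegg#xGene>"),
    o = c("<http://bio2rdf.org/ns/kegg#Enzyme>", '"beta-mannanase"',
          "<http://bio2rdf.org/cpd:C00001>", "<http://bio2rdf.org/gene:b0001>")
  )
  d <- probe_endpoint(g, dataset_id = "http://bio2rdf.org/dataset:kegg",
                      endpoint_urls = "http://kegg.example.org/sparql")
  expect_equal(d$classes$class_iri, "http://bio2rdf.org/ns/kegg#Enzyme")
  expect_equal(d$classes$label, "Enzyme")
  expect_equal(d$classes$example_resource, "http://bio2rdf.org/ec:3.2.1.161")
  expect_setequal(d$predicates$predicate_iri,
                  c(iri_value(RDF_TYPE),
                    "http://bio2rdf.org/ns/bio2rdf#synonym",
                    "http://bio2rdf.org/ns/kegg#xSubstrate",
                    "http://bio2rdf.org/ns/kegg#xGene"))
  # sampled domain class for an exclusive predicate
  syn <- d$predicates[d$predicates$predicate_iri == "http://bio2rdf.org/ns/bio2rdf#synonym", ]
  expect_equal(syn$domain_class, "http://bio2rdf.org/ns/kegg#Enzyme")
  expect_true(grepl(d$classes$uri_regex_pattern, d$classes$example_resource))
})

test_that("probing an empty graph yields an empty descriptor", {
  d <- probe_endpoint(rdf_graph(), dataset_id = "http://x/empty",
                      endpoint_urls = "http://empty.example.org/sparql")
  expect_equal(nrow(d$classes), 0)
  expect_equal(nrow(d$predicates), 0)
})

test_that("probed predicate sets equal brute-force triple enumeration", {
  fed <- gen_fed()
  for (nm in names(fed$graphs)) {
    d <- fed$catalogue$descriptors[[fed$dataset_ids[[nm]]]]
    expect_setequal(d$predicates$predicate_iri,
                    unique(sub(">$", "", sub("^<", "", fed$graphs[[nm]]$p))))
  }
})

test_that("URI patterns generalize the local identifier", {
  p <- derive_uri_pattern("http://bio2rdf.org/ec:3.2.1.161")
  expect_true(startsWith(p, "^"))
  expect_true(grepl(p, "http://bio2rdf.org/ec:3.2.1.161"))
  expect_true(grepl(p, "http://bio2rdf.org/ec:1.1.1.1"))
  expect_false(grepl(p, "http://bio2rdf.org/cpd:C00001"))
  # no local segment: exact-match pattern
  p2 <- derive_uri_pattern("http://example.org/")
  expect_true(grepl(p2, "http://example.org/"))
  expect_false(grepl(p2, "http://example.org/x"))
  # property: any IRI matches its own derived pattern
  set.seed(2024)
  for (i in 1:50) {
    iri <- paste0("http://", paste0(sample(letters, 5), collapse = ""), ".org/",
                  sample(c("ns/", "", "res:"), 1),
                  paste0(sample(c(letters, 0:9, "."), 8, replace = TRUE), collapse = ""))
    expect_true(grepl(derive_uri_pattern(iri), iri), info = iri)
  }
})

test_that("catalogue round-trips through VoID Turtle field-by-field", {
  fed <- we_fed()
  f <- withr::local_tempfile(fileext = ".ttl")
  write_catalogue(fed$catalogue, f)
  back <- read_catalogue(f)
  expect_setequal(names(back$descriptors), names(fed$catalogue$descriptors))
  for (id in names(fed$catalogue$descriptors)) {
    a <- fed$catalogue$descriptors[[id]]
    b <- back$descriptors[[id]]
    expect_equal(b$title, a$title, info = id)
    expect_equal(b$endpoint_urls, a$endpoint_urls, info = id)
    expect_equal(as.data.frame(b$classes), as.data.frame(a$classes), info = id)
    expect_equal(as.data.frame(b$predicates), as.data.frame(a$predicates), info = id)
    expect_equal(b$built_at, a$built_at, info = id)
    expect_equal(b$partial, a$partial, info = id)
  }
  # mirrors serialized as multi-valued void:sparqlEndpoint on one dataset node
  kegg <- fed$dataset_ids[["kegg"]]
  expect_length(back$descriptors[[kegg]]$endpoint_urls, 2)
  ttl <- paste(readLines(f), collapse = "\n")
  expect_true(grepl("void:sparqlEndpoint <[^>]+> , <[^>]+>", ttl))
})

test_that("indexes are exactly the inversion of descriptor contents", {
  fed <- gen_fed()
  f <- withr::local_tempfile(fileext = ".ttl")
  write_catalogue(fed$catalogue, f)
  back <- read_catalogue(f)
  rebuilt <- sparqlfed:::rebuild_indexes(back$descriptors)
  canon <- function(x) dplyr::arrange(x, dplyr::across(dplyr::everything()))
  expect_equal(canon(back$predicate_index), canon(rebuilt$predicate_index))
  expect_equal(canon(back$class_index), canon(rebuilt$class_index))
  expect_equal(canon(back$predicate_index), canon(fed$catalogue$predicate_index))
  # no orphans: every descriptor predicate/class is indexed
  for (id in names(back$descriptors)) {
    d <- back$descriptors[[id]]
    expect_true(all(d$predicates$predicate_iri %in% back$predicate_index$predicate_iri))
    expect_true(all(d$classes$class_iri %in% back$class_index$class_iri))
  }
})

test_that("predicate lookup answers the worked example and degenerate cases", {
  fed <- we_fed()
  expect_equal(predicate_lookup(fed$catalogue, "http://bio2rdf.org/ns/drugbank#drugCategory"),
               fed$dataset_ids[["drugbank"]])
  expect_equal(predicate_lookup(fed$catalogue, "http://nowhere.org/p"), character(0))
  expect_setequal(predicate_lookup(fed$catalogue, iri_value(RDF_TYPE)),
                  unname(fed$dataset_ids))
  expect_setequal(predicate_lookup(fed$catalogue, "http://purl.org/dc/elements/1.1/title"),
                  unname(fed$dataset_ids[c("kegg", "chebi")]))
})

test_that("index membership agrees with per-graph single-predicate ASK", {
  fed <- gen_fed()
  preds <- unique(fed$catalogue$predicate_index$predicate_iri)
  for (pi in preds) {
    by_index <- predicate_lookup(fed$catalogue, pi)
    by_ask <- sort(unname(fed$dataset_ids[vapply(names(fed$graphs), function(nm) {
      graph_ask(fed$graphs[[nm]], "?s", paste0("<", pi, ">"), "?o")
    }, logical(1))]))
    expect_equal(by_index, by_ask, info = pi)
  }
})

test_that("descriptor and catalogue invariants are enforced", {
  expect_error(dataset_descriptor("http://x/d", endpoint_urls = character(0)))
  d1 <- dataset_descriptor("http://x/d", endpoint_urls = "http://u1")
  expect_error(build_catalogue(list(d1, d1)), "duplicate dataset IRI")
  expect_error(probe_endpoint(rdf_graph(), dataset_id = "http://x/d"), "endpoint_urls")
})
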