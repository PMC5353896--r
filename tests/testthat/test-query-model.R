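test_that("the five-pattern drug query parses to one BGP with five patterns", {
  q <- parse_query(worked_example_query())
  pats <- query_patterns(q)
  expect_equal(nrow(pats), 5)
  expect_equal(unique(pats$bgp_id), 0L)
  expect_equal(pats$ordinal, 0:4)
  expect_equal(pats$s[1], "?drug")
  expect_equal(pats$p[1], "<http://bio2rdf.org/ns/drugbank#drugCategory>")
  expect_equal(pats$o[1], "<http://bio2rdf.org/drugbank_category:micronutrient>")
  expect_equal(pats$p[3], RDF_TYPE)
  expect_equal(pats$o[3], "<http://bio2rdf.org/ns/kegg#Drug>")
})

test_that("minimal query parses with three variable terms", {
  q <- parse_query("SELECT * WHERE { ?s ?p ?o }")
  pats <- query_patterns(q)
  expect_equal(nrow(pats), 1)
  expect_true(all(term_kind(c(pats$s, pats$p, pats$o)) == "variable"))
})

test_that("UNION branches open separate BGPs; FILTER does not", {
  q <- parse_query("
    SELECT * WHERE {
      { ?a <http://x/p> ?b . ?b <http://x/q> ?c }
      UNION
      { ?a <http://x/r> ?d . ?d <http://x/s> ?e }
    }")
  pats <- query_patterns(q)
  expect_equal(dplyr::n_distinct(pats$bgp_id), 2)
  expect_equal(nrow(pats), 4)

  qf <- parse_query("
    SELECT * WHERE {
      ?a <http://x/p> ?b .
      FILTER (?b != <http://x/nope>)
      ?a <http://x/q> ?c .
    }")
  expect_equal(dplyr::n_distinct(query_patterns(qf)$bgp_id), 1)
  expect_equal(nrow(query_patterns(qf)), 2)

  qo <- parse_query("
    SELECT * WHERE { ?a <http://x/p> ?b OPTIONAL { ?a <http://x/q> ?c } }")
  expect_equal(dplyr::n_distinct(query_patterns(qo)$bgp_id), 2)
})

test_that("parse failures are informative", {
  expect_error(parse_query(""), "empty query")
  expect_error(parse_query("SELECT * WHERE { ?s ?p }"), "line")
  expect_error(parse_query("FROB ?x"), "SELECT or ASK")
  expect_error(parse_query("SELECT * WHERE { ?s foaf:name ?o }"), "undeclared prefix")
})

test_that("worked 3-pattern drug-disease query has the published features", {
  q <- "
    PREFIX drugbank: <http://bio2rdf.org/ns/drugbank#>
    PREFIX diseasome: <http://bio2rdf.org/ns/diseasome#>
    SELECT ?name WHERE {
      ?drug drugbank:molecularWeightAverage ?weight .
      ?drug drugbank:possibleDiseaseTarget ?disease .
      ?disease diseasome:name ?name .
    }"
  f <- compute_features(q)
  expect_equal(f$bgp_count, 1)
  expect_equal(f$tp_count, 3)
  expect_equal(f$total_vertices, 7)
  expect_equal(f$join_vertices, 2)
  expect_equal(sort(f$join_vertex_names), c("?disease", "?drug"))
  expect_equal(f$ratio, 2 / 7)
  expect_equal(truncate3(f$ratio), 0.285)
  expect_equal(f$mean_join_degree, 2.0)
  expect_equal(f$clauses, character(0))
})

test_that("feature conventions: no repeats, clause detection, join positions", {
  f0 <- compute_features("SELECT * WHERE { ?s ?p ?o }")
  expect_equal(f0$total_vertices, 3)
  expect_equal(f0$join_vertices, 0)
  expect_equal(f0$ratio, 0)
  expect_equal(f0$mean_join_degree, 0)

  fe <- compute_features(parse_query("ASK { ?s <http://x/p> ?o }"))
  expect_equal(fe$tp_count, 1)

  q <- "
    SELECT DISTINCT ?a WHERE {
      { ?a <http://x/p> ?b . FILTER (REGEX(?b, \"x\")) }
      UNION
      { ?a <http://x/q> ?c OPTIONAL { ?c <http://x/r> ?d } }
    } ORDER BY ?a LIMIT 5"
  f <- compute_features(q)
  expect_setequal(f$clauses,
                  c("DISTINCT", "UNION", "FILTER", "REGEX", "OPTIONAL", "LIMIT", "ORDER BY"))

  # a repeated predicate is a join vertex under the default, not under "so"
  qtype <- "SELECT * WHERE { ?a <http://x/type> ?b . ?c <http://x/type> ?d }"
  expect_equal(compute_features(qtype)$join_vertices, 1)
  expect_equal(compute_features(qtype, join_positions = "so")$join_vertices, 0)
})

test_that("features match the occurrence-set oracle on seeded random queries", {
  set.seed(4711)
  for (i in 1:200) {
    n_union <- if (runif(1) < 0.3) sample(1:3, 1) else 0
    text <- random_bgp_query(sample(1:8, 1), n_union)
    q <- parse_query(text)
    f <- compute_features(q)
    o <- oracle_features(query_patterns(q))
    expect_equal(f$total_vertices, o$total_vertices, info = text)
    expect_equal(f$join_vertices, o$join_vertices, info = text)
    expect_equal(f$ratio, o$ratio, info = text)
    expect_equal(f$mean_join_degree, o$mean_join_degree, info = text)
    # exact rational identity before any rounding
    expect_identical(f$ratio * f$total_vertices, as.numeric(f$join_vertices))
  }
})

test_that("re-serializing and re-parsing leaves features unchanged", {
  set.seed(99)
  texts <- c(
    worked_example_query(),
    replicate(25, random_bgp_query(sample(1:6, 1), sample(0:2, 1)))
  )
  for (text in texts) {
    q1 <- parse_query(text)
    q2 <- parse_query(serialize_query(q1))
    expect_equal(tidy(compute_features(q2)), tidy(compute_features(q1)), info = text)
    expect_equal(query_patterns(q2)[, c("s", "p", "o")],
                 query_patterns(q1)[, c("s", "p", "o")], info = text)
  }
})

test_that("blank nodes in patterns count as scoped variables", {
  f <- compute_features("SELECT * WHERE { _:b <http://x/p> ?o . _:b <http://x/q> ?v }")
  expect_equal(f$total_vertices, 5)
  expect_equal(f$join_vertices, 1)
})
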