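test_that("exclusive groups of the worked example partition patterns 1-4", {
  fed <- we_fed()
  sel <- select_sources(worked_example_query(), fed$catalogue, fed$registry)
  eg <- exclusive_groups(sel)
  expect_equal(nrow(eg), 2)
  db <- eg[eg$dataset_id == fed$dataset_ids[["drugbank"]], ]
  kg <- eg[eg$dataset_id == fed$dataset_ids[["kegg"]], ]
  expect_equal(db$ordinals[[1]], c(0L, 1L))
  expect_equal(kg$ordinals[[1]], c(2L, 3L))
  # pattern 5 (ordinal 4) is in no group
  expect_false(4L %in% unlist(eg$ordinals))
})

test_that("no exclusive groups when every pattern has several relevant sources", {
  rel <- tibble::tibble(
    bgp_id = c(0L, 0L), ordinal = c(0L, 1L),
    s = c("?a", "?b"), p = c("<http://x/p>", "<http://x/q>"), o = c("?b", "?c"),
    datasets = list(c("d1", "d2"), c("d2", "d3"))
  )
  expect_equal(nrow(exclusive_groups(rel)), 0)
})

test_that("groups equal a brute-force partition on random relevance sets", {
  set.seed(77)
  ds_pool <- paste0("http://x/ds", 1:6)
  for (rep in 1:50) {
    n <- sample(1:8, 1)
    rel <- tibble::tibble(
      bgp_id = sort(sample(0:2, n, replace = TRUE)),
      s = rep("?s", n), p = rep("<http://x/p>", n), o = rep("?o", n),
      datasets = replicate(n, sample(ds_pool, sample(0:3, 1)), simplify = FALSE)
    )
    rel <- dplyr::ungroup(dplyr::mutate(dplyr::group_by(rel, bgp_id),
                                        ordinal = dplyr::row_number() - 1L))
    eg <- exclusive_groups(rel)
    # oracle: key singleton-relevance patterns by (bgp, dataset)
    singles <- rel[vapply(rel$datasets, length, integer(1)) == 1, ]
    pkey <- function(b, o) if (length(b) == 0) character(0) else paste0(b, "/", o)
    expected_keys <- unique(pkey(singles$bgp_id,
                                 vapply(singles$datasets, `[[`, character(1), 1)))
    expect_setequal(pkey(eg$bgp_id, eg$dataset_id), expected_keys)
    got_pat <- unlist(Map(function(b, o) paste0(b, "/", o), eg$bgp_id, eg$ordinals))
    expect_setequal(got_pat %||% character(0), pkey(singles$bgp_id, singles$ordinal))
  }
})

test_that("the worked example rewrites to two SERVICE groups plus a 2-branch UNION", {
  fed <- we_fed()
  sel <- select_sources(worked_example_query(), fed$catalogue, fed$registry)
  rw <- rewrite_query(worked_example_query(), sel, fed$catalogue, fed$registry)
  expect_equal(sum(rw$blocks$kind == "exclusive"), 2)
  expect_equal(sum(rw$blocks$kind == "union"), 2)
  expect_equal(rw$blocks$n_patterns[rw$blocks$kind == "exclusive"], c(2L, 2L))
  # structural check on the re-parsed SPARQL 1.1 text
  q2 <- parse_query(rw$text)
  count_nodes <- function(node, type) {
    n <- as.integer(node$type == type)
    kids <- switch(node$type,
      join = , union = node$parts,
      optional = list(node$left, node$right),
      filter = , service = list(node$inner),
      list())
    n + sum(vapply(kids, count_nodes, integer(1), type = type))
  }
  expect_equal(count_nodes(q2$algebra, "service"), 4L)
  expect_equal(count_nodes(q2$algebra, "union"), 1L)
  # the union's branches are SERVICE blocks at KEGG and ChEBI
  expect_setequal(
    rw$blocks$dataset_id[rw$blocks$kind == "union"],
    unname(fed$dataset_ids[c("kegg", "chebi")]))
})

test_that("a single-pattern single-source query becomes one SERVICE wrapper", {
  fed <- we_fed()
  q <- "SELECT * WHERE { ?c <http://bio2rdf.org/ns/chebi#formula> ?f }"
  sel <- select_sources(q, fed$catalogue, fed$registry)
  rw <- rewrite_query(q, sel, fed$catalogue, fed$registry)
  expect_equal(nrow(rw$blocks), 1)
  expect_equal(rw$blocks$kind, "exclusive")
  expect_match(rw$text, "SERVICE <http://chebi")
})

test_that("pattern multiset is conserved and the text re-parses", {
  fed <- gen_fed()
  qs <- synthesize_queries(fed, n = 25, seed = 606)
  for (text in qs) {
    sel <- suppressWarnings(select_sources(text, fed$catalogue, fed$registry))
    rw <- suppressWarnings(rewrite_query(text, sel, fed$catalogue, fed$registry))
    orig <- query_patterns(parse_query(text))
    rewr <- query_patterns(parse_query(rw$text))
    # non-exclusive patterns are duplicated across UNION branches: compare sets
    # and check each original pattern appears with multiplicity >= 1
    key <- function(df) paste(df$s, df$p, df$o)
    expect_setequal(unique(key(rewr)), unique(key(orig)))
    expect_true(all(key(orig) %in% key(rewr)), info = text)
  }
})

test_that("exclusive grouping never changes results (one-service-per-pattern mode)", {
  fed <- gen_fed()
  qs <- synthesize_queries(fed, n = 15, seed = 51)
  for (text in qs) {
    sel <- suppressWarnings(select_sources(text, fed$catalogue, fed$registry))
    grouped <- suppressWarnings(rewrite_query(text, sel, fed$catalogue, fed$registry))
    ungrouped <- suppressWarnings(
      rewrite_query(text, sel, fed$catalogue, fed$registry, group = FALSE))
    expect_gte(nrow(ungrouped$blocks), nrow(grouped$blocks))
    a <- execute_query(grouped, fed$registry)$results
    b <- execute_query(ungrouped, fed$registry)$results
    expect_true(same_solutions(a, b), info = text)
  }
})

test_that("empty relevance sets yield empty blocks, or fail under strict", {
  fed <- we_fed()
  q <- "SELECT * WHERE { ?s <http://nowhere.org/absent> ?o }"
  sel <- suppressWarnings(select_sources(q, fed$catalogue, fed$registry))
  expect_warning(rw <- rewrite_query(q, sel, fed$catalogue, fed$registry),
                 "empty relevance")
  expect_equal(rw$blocks$kind, "empty")
  res <- execute_query(rw, fed$registry)
  expect_equal(nrow(res$results), 0)
  expect_error(
    suppressWarnings(rewrite_query(q, sel, fed$catalogue, fed$registry, strict = TRUE)),
    "strict")
})

test_that("filters are pushed into the single SERVICE block binding their variables", {
  fed <- we_fed()
  q <- paste0("SELECT * WHERE { ?c <http://bio2rdf.org/ns/chebi#formula> ?f ",
              "FILTER (CONTAINS(?f, \"C10\")) }")
  sel <- select_sources(q, fed$catalogue, fed$registry)
  rw <- rewrite_query(q, sel, fed$catalogue, fed$registry)
  # FILTER line sits inside the SERVICE braces
  expect_match(gsub("\n", " ", rw$text),
               "SERVICE <http://chebi[^{]*\\{[^}]*FILTER")
  res <- execute_query(rw, fed$registry)
  expect_equal(nrow(res$results), 1)
})
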