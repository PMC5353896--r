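# Independent brute-force oracles and small generators used across tests.
# These deliberately avoid the package's own evaluation/feature code paths:
# plain base-R loops over pattern tables and triple tables.

`%||%` <- function(a, b) if (is.null(a)) b else a

# occurrence-set feature oracle: tabulate, per distinct term, the set of
# patterns containing it (variables/blanks canonicalised by binding name)
oracle_features <- function(pats) {
  canon <- function(t) {
    if (startsWith(t, "?")) t
    else if (startsWith(t, "_:")) paste0("?.", substring(t, 3))
    else t
  }
  occ <- list()  # vertex -> character vector of "bgp/ordinal" keys
  bgp_of <- list()
  for (i in seq_len(nrow(pats))) {
    key <- paste0(pats$bgp_id[i], "/", pats$ordinal[i])
    for (t in c(pats$s[i], pats$p[i], pats$o[i])) {
      v <- canon(t)
      occ[[v]] <- union(occ[[v]], key)
      bgp_of[[v]] <- union(bgp_of[[v]], pats$bgp_id[i])
    }
  }
  tv <- length(occ)
  degrees <- numeric(0)
  for (v in names(occ)) {
    per_bgp <- table(sub("/.*", "", occ[[v]]))
    d <- max(per_bgp)
    if (d >= 2) degrees <- c(degrees, d)
  }
  list(total_vertices = tv, join_vertices = length(degrees),
       ratio = if (tv > 0) length(degrees) / tv else 0,
       mean_join_degree = if (length(degrees) > 0) mean(degrees) else 0)
}

# direct per-graph triple pattern match (independent of match_pattern):
# does `graph` contain a triple satisfying the pattern?
oracle_pattern_matches <- function(graph, s, p, o) {
  ok <- rep(TRUE, nrow(graph))
  binds <- list()
  for (pos in c("s", "p", "o")) {
    t <- get(pos)
    if (!startsWith(t, "?") && !startsWith(t, "_:")) {
      ok <- ok & graph[[pos]] == t
    } else {
      binds[[t]] <- c(binds[[t]], pos)
    }
  }
  # repeated-variable equality
  for (v in names(binds)) {
    cols <- binds[[v]]
    if (length(cols) > 1) {
      for (k in seq_along(cols)[-1]) ok <- ok & graph[[cols[1]]] == graph[[cols[k]]]
    }
  }
  any(ok)
}

# relevance oracle: datasets whose graph matches the pattern directly
oracle_relevance <- function(fed, s, p, o) {
  hit <- vapply(names(fed$graphs), function(nm) {
    oracle_pattern_matches(fed$graphs[[nm]], s, p, o)
  }, logical(1))
  sort(unname(fed$dataset_ids[names(fed$graphs)[hit]]))
}

# random BGP query text over an abstract vocabulary (for feature properties)
random_bgp_query <- function(n_pat, n_union = 0) {
  vars <- paste0("?x", 1:6)
  iris <- paste0("<http://ex.org/", c("p1", "p2", "p3", "C", "a", "b"), ">")
  lits <- c('"v1"', '"v2"')
  term <- function(kinds) {
    pool <- c(if ("v" %in% kinds) vars, if ("i" %in% kinds) iris,
              if ("l" %in% kinds) lits)
    sample(pool, 1)
  }
  mk_pats <- function(k) {
    paste(vapply(seq_len(k), function(i) {
      paste(term(c("v", "i")), term(c("v", "i")), term(c("v", "i", "l")), ".")
    }, character(1)), collapse = " ")
  }
  if (n_union > 0) {
    paste0("SELECT * WHERE { { ", mk_pats(n_pat), " } UNION { ", mk_pats(n_union), " } }")
  } else {
    paste0("SELECT * WHERE { ", mk_pats(n_pat), " }")
  }
}

# shared fixtures, built once per test run
we_fed <- local({
  val <- NULL
  function() {
    if (is.null(val)) val <<- worked_example_fixture()
    val
  }
})

gen_fed <- local({
  val <- NULL
  function() {
    if (is.null(val)) val <<- generate_federation(topology_config(seed = 42))
    val
  }
})
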