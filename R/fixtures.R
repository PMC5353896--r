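#' Topology of a synthetic life-science federation
#'
#' Describes the shape of a generated multi-endpoint federation in the style
#' of the public life-science linked-data cloud: every dataset has its own
#' classes, typed instances and exclusive predicates; a small set of common
#' predicates (always including `rdf:type`, plus `rdfs:label` by default)
#' occurs in every dataset; cross-dataset object links connect instances of
#' different datasets (the joins federated queries exercise); and
#' literal-overlap pairs make two different predicates in two datasets share
#' literal values (the way a chemistry dataset's "title" matches a drug
#' dataset's "genericName").
#'
#' @param n_datasets Number of federation members.
#' @param exclusive_predicates_per_dataset Predicates occurring in exactly
#'   one dataset.
#' @param shared_predicates Predicate IRIs present in every dataset
#'   (`rdf:type` is always included).
#' @param cross_links Tibble/data frame with columns `source`, `target`,
#'   `predicate` (dataset names and a bare predicate IRI); `NULL` gives a
#'   default chain linking each dataset to the next.
#' @param literal_overlaps Tibble with columns `dataset_a`, `predicate_a`,
#'   `dataset_b`, `predicate_b`; `NULL` gives one default overlapping pair
#'   when the federation has at least three members.
#' @param instances_per_class Typed instances generated per class.
#' @param classes_per_dataset Classes per dataset.
#' @param seed Integer seed; fully determines the generated federation.
#' @return A `topology_config` list.
#' @export
topology_config <- function(n_datasets = 10,
                            exclusive_predicates_per_dataset = 3,
                            shared_predicates = iri_value(RDFS_LABEL),
                            cross_links = NULL,
                            literal_overlaps = NULL,
                            instances_per_class = 6,
                            classes_per_dataset = 2,
                            seed = 42) {
  stopifnot(n_datasets >= 1, instances_per_class >= 1, classes_per_dataset >= 1)
  names_pool <- c("drugbank", "kegg", "chebi", "sider", "diseasome", "dailymed",
                  "linkedct", "medicare", "affymetrix", "tcga")
  ds_names <- if (n_datasets <= length(names_pool)) names_pool[seq_len(n_datasets)]
              else c(names_pool, paste0("dataset", seq_len(n_datasets - length(names_pool))))
  shared_predicates <- union(iri_value(RDF_TYPE), shared_predicates)
  if (is.null(cross_links)) {
    cross_links <- if (n_datasets >= 2) {
      tibble::tibble(
        source = ds_names[seq_len(n_datasets - 1)],
        target = ds_names[1 + seq_len(n_datasets - 1)],
        predicate = paste0("http://bio2rdf.org/ns/", ds_names[seq_len(n_datasets - 1)], "#x",
                           toupper(substr(ds_names[1 + seq_len(n_datasets - 1)], 1, 1)),
                           substring(ds_names[1 + seq_len(n_datasets - 1)], 2))
      )
    } else tibble::tibble(source = character(), target = character(), predicate = character())
  }
  if (is.null(literal_overlaps)) {
    literal_overlaps <- if (n_datasets >= 3) {
      tibble::tibble(
        dataset_a = ds_names[1], predicate_a = paste0("http://bio2rdf.org/ns/", ds_names[1], "#genericName"),
        dataset_b = ds_names[3], predicate_b = paste0("http://bio2rdf.org/ns/", ds_names[3], "#title")
      )
    } else {
      tibble::tibble(dataset_a = character(), predicate_a = character(),
                     dataset_b = character(), predicate_b = character())
    }
  }
  bad <- setdiff(c(cross_links$source, cross_links$target,
                   literal_overlaps$dataset_a, literal_overlaps$dataset_b), ds_names)
  if (length(bad) > 0) {
    stop("topology names unknown dataset(s): ", paste(unique(bad), collapse = ", "),
         call. = FALSE)
  }
  structure(
    list(n_datasets = n_datasets, dataset_names = ds_names,
         exclusive_predicates_per_dataset = exclusive_predicates_per_dataset,
         shared_predicates = shared_predicates, cross_links = tibble::as_tibble(cross_links),
         literal_overlaps = tibble::as_tibble(literal_overlaps),
         instances_per_class = instances_per_class,
         classes_per_dataset = classes_per_dataset, seed = seed),
    class = "topology_config"
  )
}

with_seed <- function(seed, code) {
  genv <- globalenv()
  old <- if (exists(".Random.seed", envir = genv, inherits = FALSE))
    get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = genv, inherits = FALSE))
        rm(".Random.seed", envir = genv)
    } else assign(".Random.seed", old, envir = genv)
  })
  set.seed(seed)
  force(code)
}

fed_dataset_iri <- function(name) paste0("http://bio2rdf.org/dataset:", name)
fed_primary_url <- function(name) paste0("http://", name, ".example.org/sparql")

#' Generate a synthetic multi-endpoint federation
#'
#' Builds the per-dataset RDF graphs described by a [topology_config()],
#' registers each dataset as an in-process endpoint (the first dataset also
#' gets a slower mirror URL, exercising mirror selection), probes every
#' graph into a catalogue, and exposes a ground-truth function mapping any
#' triple pattern to the datasets whose graph matches it. Instance IRIs are
#' disjoint across datasets, so no identical triple exists in two members
#' and federated results can be compared to merged-graph evaluation as
#' exact multisets. Output is fully deterministic under the config seed.
#'
#' @param config A [topology_config()].
#' @return A `synthetic_federation`: list with `config`, `dataset_ids`
#'   (named by dataset name), `graphs` (named list of triple tibbles),
#'   `registry`, `catalogue`, `endpoints` (dataset id -> primary URL) and
#'   `truth` (`function(s, p, o)` returning the matching dataset ids, read
#'   live from the registry so deregistered endpoints drop out).
#' @export
generate_federation <- function(config = topology_config()) {
  stopifnot(inherits(config, "topology_config"))
  with_seed(config$seed, {
    ds_names <- config$dataset_names
    ds_ids <- stats::setNames(fed_dataset_iri(ds_names), ds_names)
    shared_non_type <- setdiff(config$shared_predicates, iri_value(RDF_TYPE))
    overlap_values <- if (nrow(config$literal_overlaps) > 0) {
      lapply(seq_len(nrow(config$literal_overlaps)), function(i) {
        paste0("shared term ", i, ".", seq_len(3))
      })
    } else list()
    graphs <- list()
    instances <- list()  # per dataset: encoded instance IRIs
    for (di in seq_along(ds_names)) {
      nm <- ds_names[di]
      vocab <- paste0("http://bio2rdf.org/ns/", nm, "#")
      s <- character(0); p <- character(0); o <- character(0)
      add <- function(ss, pp, oo) {
        n <- max(length(ss), length(pp), length(oo))
        s <<- c(s, rep_len(ss, n)); p <<- c(p, rep_len(pp, n)); o <<- c(o, rep_len(oo, n))
      }
      inst_all <- character(0)
      for (ci in seq_len(config$classes_per_dataset)) {
        class_iri <- rdf_iri(paste0(vocab, "Class", ci))
        inst <- rdf_iri(sprintf("http://bio2rdf.org/%s:%s%04d", nm, LETTERS[ci],
                                seq_len(config$instances_per_class)))
        add(inst, RDF_TYPE, class_iri)
        for (sp in shared_non_type) {
          add(inst, rdf_iri(sp),
              rdf_literal(paste(nm, "entity", LETTERS[ci], seq_along(inst))))
        }
        inst_all <- c(inst_all, inst)
      }
      for (k in seq_len(config$exclusive_predicates_per_dataset)) {
        pred <- rdf_iri(paste0(vocab, "p", k))
        subj <- sample(inst_all, max(2L, ceiling(length(inst_all) / 2)))
        if (k %% 2 == 1) {
          add(subj, pred, rdf_literal(paste0(nm, " value ", k, ".", seq_along(subj))))
        } else {
          add(subj, pred, sample(inst_all, length(subj), replace = TRUE))
        }
      }
      graphs[[nm]] <- rdf_graph(s, p, o)
      instances[[nm]] <- inst_all
    }
    # cross-dataset object links
    for (i in seq_len(nrow(config$cross_links))) {
      cl <- config$cross_links[i, ]
      src_inst <- sample(instances[[cl$source]], min(3L, length(instances[[cl$source]])))
      tgt_inst <- sample(instances[[cl$target]], length(src_inst), replace = TRUE)
      graphs[[cl$source]] <- dplyr::distinct(dplyr::bind_rows(
        graphs[[cl$source]],
        tibble::tibble(s = src_inst, p = rdf_iri(cl$predicate), o = tgt_inst)))
    }
    # shared-literal overlaps
    for (i in seq_len(nrow(config$literal_overlaps))) {
      ov <- config$literal_overlaps[i, ]
      vals <- rdf_literal(overlap_values[[i]])
      for (side in list(c(ov$dataset_a, ov$predicate_a), c(ov$dataset_b, ov$predicate_b))) {
        subj <- sample(instances[[side[1]]], length(vals), replace = TRUE)
        graphs[[side[1]]] <- dplyr::distinct(dplyr::bind_rows(
          graphs[[side[1]]],
          tibble::tibble(s = subj, p = rdf_iri(side[2]), o = vals)))
      }
    }
    registry <- endpoint_registry()
    endpoints <- stats::setNames(fed_primary_url(ds_names), ds_ids)
    latencies <- sample(5:60, length(ds_names), replace = TRUE)
    descriptors <- vector("list", length(ds_names))
    for (di in seq_along(ds_names)) {
      nm <- ds_names[di]
      urls <- endpoints[[ds_ids[[nm]]]]
      register_endpoint(registry, urls, graphs[[nm]], latency_ms = latencies[di])
      if (di == 1) {
        mirror <- paste0("http://mirror.", nm, ".example.org/sparql")
        register_endpoint(registry, mirror, graphs[[nm]], latency_ms = latencies[di] + 50)
        urls <- c(urls, mirror)
      }
      descriptors[[di]] <- probe_endpoint(graphs[[nm]], dataset_id = ds_ids[[nm]],
                                          endpoint_urls = urls, title = nm)
    }
    catalogue <- build_catalogue(descriptors)
    fed <- list(config = config, dataset_ids = ds_ids, graphs = graphs,
                registry = registry, catalogue = catalogue, endpoints = endpoints)
    fed$truth <- function(s, p, o) {
      hit <- vapply(names(fed$dataset_ids), function(nm) {
        url <- fed$endpoints[[fed$dataset_ids[[nm]]]]
        ep <- registry_get(fed$registry, url)
        !is.null(ep) && graph_ask(ep$graph, s, p, o)
      }, logical(1))
      sort(unname(fed$dataset_ids[names(fed$dataset_ids)[hit]]))
    }
    structure(fed, class = "synthetic_federation")
  })
}

#' @export
print.synthetic_federation <- function(x, ...) {
  cat("<synthetic_federation> ", length(x$graphs), " dataset(s), ",
      sum(vapply(x$graphs, nrow, integer(1))), " triples total\n", sep = "")
  invisible(x)
}

# --- the worked five-pattern drug query ------------------------------------

WE_NS <- list(
  drugbank = "http://bio2rdf.org/ns/drugbank#",
  drugcategory = "http://bio2rdf.org/drugbank_category:",
  kegg = "http://bio2rdf.org/ns/kegg#",
  chebi = "http://bio2rdf.org/ns/chebi#",
  bio2rdf = "http://bio2rdf.org/ns/bio2rdf#",
  purl = "http://purl.org/dc/elements/1.1/"
)

#' The five-pattern drug federation query
#'
#' The classic cross-dataset drug query: micronutrient drug categories and
#' CAS registry numbers live only in the drug dataset, drug entries and
#' cross-references only in the pathway dataset, and compound titles in both
#' the pathway and the chemistry dataset — so its per-pattern relevance
#' profile over [worked_example_fixture()] is (1, 1, 1, 1, 2).
#'
#' @return SPARQL text (five triple patterns, one BGP).
#' @export
worked_example_query <- function() {
  paste(
    sprintf("PREFIX drugbank: <%s>", WE_NS$drugbank),
    sprintf("PREFIX drugcategory: <%s>", WE_NS$drugcategory),
    sprintf("PREFIX kegg: <%s>", WE_NS$kegg),
    sprintf("PREFIX bio2rdf: <%s>", WE_NS$bio2rdf),
    sprintf("PREFIX purl: <%s>", WE_NS$purl),
    sprintf("PREFIX rdf: <%s>", NS_RDF),
    "SELECT ?drug ?keggDrug ?title WHERE {",
    "  ?drug drugbank:drugCategory drugcategory:micronutrient .",
    "  ?drug drugbank:casRegistryNumber ?id .",
    "  ?keggDrug rdf:type kegg:Drug .",
    "  ?keggDrug bio2rdf:xRef ?id .",
    "  ?keggDrug purl:title ?title .",
    "}",
    sep = "\n"
  )
}

#' Ten-dataset fixture for the worked five-pattern query
#'
#' Builds a ten-dataset federation named after the major life-science
#' members (DrugBank, KEGG, ChEBI, Sider, Diseasome, Dailymed, LinkedCT,
#' Medicare, Affymetrix, TCGA) in which, by construction: the drug-category
#' predicate (with a micronutrient category object) and the CAS-number
#' predicate occur only in the DrugBank graph; `kegg:Drug` instances and
#' the cross-reference predicate occur only in the KEGG graph; the title
#' predicate occurs in both KEGG and ChEBI; `rdf:type` and `rdfs:label`
#' occur in all ten graphs; and the merged graph yields at least one
#' solution for [worked_example_query()]. The KEGG endpoint additionally
#' has a slower mirror URL.
#'
#' @param seed Seed for the incidental content of the seven filler
#'   datasets.
#' @return A `synthetic_federation` (see [generate_federation()]).
#' @export
worked_example_fixture <- function(seed = 7) {
  with_seed(seed, {
    ds_names <- c("drugbank", "kegg", "chebi", "sider", "diseasome", "dailymed",
                  "linkedct", "medicare", "affymetrix", "tcga")
    ds_ids <- stats::setNames(fed_dataset_iri(ds_names), ds_names)
    iri <- function(ns, local) rdf_iri(paste0(WE_NS[[ns]], local))
    cas <- c("58-85-5", "59-67-6", "68-26-8")

    graphs <- list()
    # DrugBank: categories + CAS registry numbers (exclusive)
    db_drug <- rdf_iri(paste0("http://bio2rdf.org/drugbank:DB", sprintf("%05d", 118 + seq_len(3))))
    graphs$drugbank <- rdf_graph(
      s = c(db_drug, db_drug, db_drug[1:2], db_drug[3], db_drug),
      p = c(rep(RDF_TYPE, 3), rep(iri("drugbank", "casRegistryNumber"), 3),
            rep(iri("drugbank", "drugCategory"), 3), rep(RDFS_LABEL, 3)),
      o = c(rep(iri("drugbank", "Drug"), 3), rdf_literal(cas),
            rep(iri("drugcategory", "micronutrient"), 2), iri("drugcategory", "vitamin"),
            rdf_literal(c("Biotin", "Niacin", "Retinol")))
    )
    # KEGG: kegg:Drug instances, xRef to the CAS literals, titles (exclusive
    # except the title predicate, shared with ChEBI)
    kegg_drug <- rdf_iri(paste0("http://bio2rdf.org/dr:D00", c("030", "049", "069")))
    graphs$kegg <- rdf_graph(
      s = c(kegg_drug, kegg_drug, kegg_drug, kegg_drug),
      p = c(rep(RDF_TYPE, 3), rep(iri("bio2rdf", "xRef"), 3),
            rep(iri("purl", "title"), 3), rep(RDFS_LABEL, 3)),
      o = c(rep(iri("kegg", "Drug"), 3), rdf_literal(cas),
            rdf_literal(c("Biotin", "Nicotinic acid", "Retinol")),
            rdf_literal(c("D00030", "D00049", "D00069")))
    )
    # ChEBI: compounds with titles (title shared with KEGG) and a formula
    chebi_cpd <- rdf_iri(paste0("http://bio2rdf.org/chebi:", c(15956, 15940, 17336)))
    graphs$chebi <- rdf_graph(
      s = c(chebi_cpd, chebi_cpd, chebi_cpd, chebi_cpd),
      p = c(rep(RDF_TYPE, 3), rep(iri("purl", "title"), 3),
            rep(iri("chebi", "formula"), 3), rep(RDFS_LABEL, 3)),
      o = c(rep(iri("chebi", "Compound"), 3),
            rdf_literal(c("Biotin", "Nicotinic acid", "Vitamin A")),
            rdf_literal(c("C10H16N2O3S", "C6H5NO2", "C20H30O")),
            rdf_literal(c("CHEBI:15956", "CHEBI:15940", "CHEBI:17336")))
    )
    # seven filler datasets: own class, instances, one exclusive predicate
    for (nm in ds_names[-(1:3)]) {
      vocab <- paste0("http://bio2rdf.org/ns/", nm, "#")
      inst <- rdf_iri(sprintf("http://bio2rdf.org/%s:E%04d", nm, seq_len(3)))
      graphs[[nm]] <- rdf_graph(
        s = c(inst, inst, inst),
        p = c(rep(RDF_TYPE, 3), rep(rdf_iri(paste0(vocab, "p1")), 3), rep(RDFS_LABEL, 3)),
        o = c(rep(rdf_iri(paste0(vocab, "Record")), 3),
              rdf_literal(paste0(nm, " value ", seq_len(3))),
              rdf_literal(paste(nm, "record", seq_len(3))))
      )
    }

    registry <- endpoint_registry()
    endpoints <- stats::setNames(fed_primary_url(ds_names), ds_ids)
    latencies <- stats::setNames(sample(5:40, length(ds_names)), ds_names)
    descriptors <- vector("list", length(ds_names))
    for (di in seq_along(ds_names)) {
      nm <- ds_names[di]
      urls <- endpoints[[ds_ids[[nm]]]]
      register_endpoint(registry, urls, graphs[[nm]], latency_ms = latencies[[nm]])
      if (nm == "kegg") {
        mirror <- "http://mirror.kegg.example.org/sparql"
        register_endpoint(registry, mirror, graphs[[nm]], latency_ms = latencies[[nm]] + 60)
        urls <- c(urls, mirror)
      }
      descriptors[[di]] <- probe_endpoint(graphs[[nm]], dataset_id = ds_ids[[nm]],
                                          endpoint_urls = urls, title = nm)
    }
    catalogue <- build_catalogue(descriptors)
    fed <- list(config = NULL, dataset_ids = ds_ids, graphs = graphs,
                registry = registry, catalogue = catalogue, endpoints = endpoints)
    fed$truth <- function(s, p, o) {
      hit <- vapply(names(fed$dataset_ids), function(nm) {
        url <- fed$endpoints[[fed$dataset_ids[[nm]]]]
        ep <- registry_get(fed$registry, url)
        !is.null(ep) && graph_ask(ep$graph, s, p, o)
      }, logical(1))
      sort(unname(fed$dataset_ids[names(fed$dataset_ids)[hit]]))
    }
    structure(fed, class = "synthetic_federation")
  })
}

# --- random federated query synthesis --------------------------------------

#' Synthesize random federated queries over a fixture federation
#'
#' Draws connected basic graph patterns from the merged federation graph
#' (walk-based, so joins follow real cross-dataset links), optionally adds
#' a CONTAINS/REGEX filter on a literal-binding variable, a two-branch
#' UNION, or DISTINCT. Used for the property that federated execution
#' equals merged-graph evaluation.
#'
#' @param fed A `synthetic_federation`.
#' @param n Number of queries.
#' @param seed Seed.
#' @param kinds Query shapes to draw from.
#' @return Character vector of SPARQL texts.
#' @export
synthesize_queries <- function(fed, n = 100, seed = 1,
                               kinds = c("bgp", "filter", "union", "distinct")) {
  merged <- merge_graphs(fed$graphs)
  with_seed(seed, {
    vapply(seq_len(n), function(i) synth_one(merged, kinds), character(1))
  })
}

synth_bgp <- function(merged, k, var_start = 0L) {
  nv <- var_start
  var_of <- character(0)
  newvar <- function() { nv <<- nv + 1L; paste0("?v", nv) }
  pats <- character(0)
  used <- character(0)
  add_pattern <- function(tr) {
    if (!tr$s %in% names(var_of)) var_of[[tr$s]] <<- newvar()
    s_t <- var_of[[tr$s]]
    o_t <- if (stats::runif(1) < 0.6) {
      if (!tr$o %in% names(var_of)) var_of[[tr$o]] <<- newvar()
      var_of[[tr$o]]
    } else tr$o
    pats <<- c(pats, paste(s_t, tr$p, o_t, "."))
    used <<- union(used, c(tr$s, tr$o))
  }
  add_pattern(merged[sample(nrow(merged), 1), ])
  for (j in seq_len(k - 1)) {
    touch <- merged[merged$s %in% used | merged$o %in% used, , drop = FALSE]
    tr <- if (nrow(touch) > 0 && stats::runif(1) < 0.85) {
      touch[sample(nrow(touch), 1), ]
    } else merged[sample(nrow(merged), 1), ]
    add_pattern(tr)
  }
  # a variable known to bind at least one literal, for filters
  lit_bind <- NULL
  lits <- names(var_of)[startsWith(names(var_of), "\"")]
  if (length(lits) > 0) {
    pick <- sample(lits, 1)
    lit_bind <- list(var = var_of[[pick]], value = literal_parts(pick)$lexical)
  }
  list(patterns = pats, n_vars = nv, lit_bind = lit_bind)
}

synth_one <- function(merged, kinds) {
  kind <- sample(kinds, 1)
  if (kind == "union") {
    a <- synth_bgp(merged, sample(1:2, 1))
    b <- synth_bgp(merged, sample(1:2, 1), var_start = a$n_vars)
    return(paste0("SELECT * WHERE { { ", paste(a$patterns, collapse = " "),
                  " } UNION { ", paste(b$patterns, collapse = " "), " } }"))
  }
  g <- synth_bgp(merged, sample(2:4, 1))
  body <- paste(g$patterns, collapse = " ")
  if (kind == "filter" && !is.null(g$lit_bind)) {
    frag <- substr(g$lit_bind$value, 1, min(4, nchar(g$lit_bind$value)))
    body <- if (grepl("^[A-Za-z0-9 ]+$", frag)) {
      paste0(body, " FILTER (REGEX(", g$lit_bind$var, ", ",
             rdf_literal(sub("\\s+$", "", frag)), ", \"i\"))")
    } else {
      paste0(body, " FILTER (CONTAINS(", g$lit_bind$var, ", ",
             rdf_literal(frag), "))")
    }
  }
  head <- if (kind == "distinct") "SELECT DISTINCT * WHERE { " else "SELECT * WHERE { "
  paste0(head, body, " }")
}

#' Compare two solution multisets
#'
#' Order-insensitive multiset equality of two solution tibbles (the federated
#' vs merged-graph comparison): same columns, same rows with the same
#' multiplicities.
#'
#' @param a,b Solution tibbles (or logicals, for ASK).
#' @return Logical scalar.
#' @export
same_solutions <- function(a, b) {
  if (is.logical(a) || is.logical(b)) return(identical(a, b))
  if (!setequal(names(a), names(b))) return(FALSE)
  canon <- function(x, cols) {
    x <- as.data.frame(x)[, cols, drop = FALSE]
    if (nrow(x) == 0) return(x)
    x[do.call(order, c(as.list(x), list(method = "radix"))), , drop = FALSE]
  }
  cols <- sort(names(a))
  ca <- canon(a, cols); cb <- canon(b, cols)
  nrow(ca) == nrow(cb) && (nrow(ca) == 0 || isTRUE(all.equal(
    unname(as.list(ca)), unname(as.list(cb)), check.attributes = FALSE)))
}
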