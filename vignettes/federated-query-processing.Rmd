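---
title: "Federated SPARQL query processing with sparqlfed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Federated SPARQL query processing with sparqlfed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sparqlfed)
```

## The problem

Life-science reference data is distributed over many independent SPARQL
endpoints whose contents complement each other: a drug knowledge base
carries categories and registry numbers, a pathway resource carries drug
entries and cross-references, a chemistry resource carries compound titles,
and so on. A query touching several of them must be decomposed, routed to
the right endpoints, executed remotely, and re-joined — while a scientist
still expects the answer a single merged triple store would give. That
merged-store answer is the correctness yardstick used throughout this
package: for every supported query shape, federated execution must return
the identical solution multiset.

`sparqlfed` implements the full pipeline — endpoint cataloguing,
triple-pattern-wise source selection with ASK pruning, exclusive-group
SPARQL 1.1 rewriting, and instrumented execution — against a registry of
in-process RDF graphs, so the whole system is exercised without a network.
A remote SPARQL-protocol transport can be plugged into the registry through
the same resolver interface, but nothing in the package requires one.

## The catalogue

`probe_endpoint()` summarises one endpoint into a dataset descriptor:

* every class with typed instances, labelled by the final URI segment
  (after the last `#`, `:` or `/`), with one example resource and a URI
  regex pattern generalized from it (`derive_uri_pattern()` keeps the IRI
  up to the last delimiter of the local identifier and wildcards the
  rest, so `http://bio2rdf.org/ec:3.2.1.161` generalizes to all `ec:`
  resources);
* every predicate, with a domain class and range class sampled from
  `rdf:type` assertions *inside the same graph* — no HTTP dereferencing of
  object URIs, which keeps probing testable offline (a dereferencing
  transport could be added behind the same probe interface);
* the endpoint URLs, primary first, mirrors after.

Probe budgets default to one example resource per class, a page size of
10 000 distinct classes/predicates (beyond which the descriptor is flagged
partial), and a 60 s per-request timeout for remote transports — the
endpoint-side execution cap conventionally used for public life-science
endpoints. Catalogue staleness is surfaced, not solved: descriptors carry
a build timestamp and are refreshed only by re-probing.

The catalogue serializes to VoID/Turtle: one `void:Dataset` per
descriptor, multi-valued `void:sparqlEndpoint` for mirrors, top-level
`void:class` links, and per-class/per-predicate partitions as blank-node
property lists. VoID has no canonical slot for a *predicate's* example
object, so literal examples ride on `rdf:value` inside the property
partition — a documented convention of this package, chosen so the
write-read round trip is the identity on every descriptor field.
Lookups (`predicate_lookup()`, `class_lookup()`) run over inverted indexes
that are rebuilt from descriptors and checked against them by inversion in
the tests.

## Source selection

`select_sources()` is a literal two-step implementation:

1. *Index step.* A pattern with a variable predicate gets all datasets as
   candidates (common predicates such as `rdf:type` behave the same way in
   practice, since every dataset lists them). A bound predicate gets the
   predicate-index entry.
2. *ASK step.* If the pattern's subject **or** object is bound, one
   `ASK { pattern }` goes to each candidate and false-answering candidates
   are removed. The condition is only on subject/object boundness — an
   unbound predicate does not exempt a pattern from pruning.

Accounting follows the standard federation metrics: TTPWSS is the sum of
final relevance-set sizes; #AR counts ASK requests *issued* (requests, not
responses, so the number is unambiguous under failures); SST is reported
both in total and split into index and ASK components, since published
figures do not always say whether network time is included. ASKs are
issued sequentially — concurrency would not change any reported number.

Three policies are deliberately explicit:

* datasets with no live endpoint are removed before pruning (the
  preemptive availability test); this filter can be disabled for
  accounting experiments;
* an ASK transport failure either drops the dataset (recorded) or aborts,
  per `ask_policy`;
* no ASK-result cache exists by default, matching cold-cache accounting;
  the index-free cold baseline is available as
  `index_free_ask_count()` = datasets × patterns.

A pattern whose final relevance set is empty is kept, with a warning: it
rewrites to a block with no solutions (`FILTER(false)`), so the federated
answer matches the merged-graph answer (also empty for that BGP) instead
of silently dropping the pattern.

## Exclusive groups and rewriting

Within one BGP, the patterns whose relevance set is exactly `{D}` form
D's exclusive group. The group executes at D as a single conjunctive
sub-query: no other source holds matching triples for those patterns, so
no solution can be lost, while D's own join discards irrelevant
intermediate results before they cross the network. `rewrite_query()`
emits one `SERVICE` block per exclusive group and, for every remaining
pattern, a `UNION` of single-pattern `SERVICE` blocks over its relevant
datasets.

Design choices where the construction is genuinely open:

* **Groups never span a BGP boundary.** OPTIONAL and UNION branches are
  separate BGPs, so the OPTIONAL/UNION operators always stay in the outer
  query. Left-join semantics across sources is the one federation
  subtlety this package does not claim to solve optimally; equivalence is
  guaranteed (and property-tested) for BGP/FILTER/UNION/DISTINCT queries,
  with OPTIONAL executed best-effort under the same evaluator on both
  sides of the comparison.
* **Filter placement.** A FILTER whose variables are all bound inside
  exactly one SERVICE block is pushed into that block (less transfer,
  same semantics); otherwise it stays at its original level.
* **Block order.** Blocks are emitted in ascending order of the smallest
  pattern ordinal they contain; join *optimization* is left to the
  executing engine, as is usual when the rewritten query is handed to a
  stock SPARQL 1.1 evaluator.
* **Mirrors.** Each dataset is addressed through its lowest-latency live
  URL, ties broken lexicographically so runs are reproducible.
* Variables are never renamed and the original prefix declarations are
  re-emitted verbatim, so the rewritten text stays diffable against the
  input.

## Execution, provenance, availability

`execute_query()` evaluates the rewritten algebra with every SERVICE
invocation wrapped in instrumentation: start/end timestamps, elapsed time,
solution-row count and status. One record is written per SERVICE block in
the plan (not per low-level request — the in-process transport has no
pagination, and the convention is documented rather than left ambiguous).
"Triples returned" is interpreted as solution rows: SERVICE returns
bindings, not triples. A down endpoint contributes an empty solution set
plus a `status = "down"` record — partial results — unless
`strict = TRUE` aborts. The per-query record is cached for ten minutes,
or until the same session key issues its next query; the clock is
injectable, so expiry is unit-tested rather than slept through.

`check_availability()` probes endpoints with a trivial ASK and writes
latency/up/initialized/last-checked per URL into the `EndpointData`
graph — ordinary RDF, queryable with `run_sparql()`, and re-written (not
appended) per check cycle. Endpoint latencies in the registry are
configured, deterministic values rather than wall-clock measurements;
that makes "select the lowest-latency live mirror" a testable function
instead of a race. Wall-clock time still flows into provenance and SST.

Result sets export as text, CSV, TSV, JSON, Turtle and XML
(`write_results()`), the formats a query web front end would offer.

## The SPARQL subset and its evaluator

No R package on this stack provides SPARQL or general RDF handling, so the
engine is self-contained and its scope is explicit: SELECT and ASK forms;
basic graph patterns with `;`/`,` abbreviations and `a`; FILTER
expressions (comparisons, boolean operators, arithmetic, `REGEX`,
`BOUND`, `STR`, `LANG`, `CONTAINS`, `STRSTARTS`, `isIRI`, `isLiteral`);
OPTIONAL, UNION, SERVICE (with SILENT); DISTINCT, ORDER BY,
LIMIT/OFFSET. Property paths, aggregation, subqueries and VALUES are out
of scope. Terms are carried in an N-Triples-style string encoding, graphs
and solution multisets are tibbles, BGP joins are many-to-many equijoins
on shared variables (with a compatibility join fallback once OPTIONAL has
introduced unbound values), and blank nodes in queries act as
non-projectable variables. Numeric comparison applies to literals with
numeric XSD datatypes; everything else compares by lexical form, and type
errors make a filter row fail, mirroring SPARQL's error semantics closely
enough that both sides of every equivalence test use identical rules.

## Synthetic federations: what the generator states

`generate_federation()` builds the ten-member topology the tests assume,
seeded and fully deterministic:

* ten datasets named after the familiar life-science federation members,
  each with 2 classes × 6 typed instances and 3 exclusive predicates —
  hundreds of triples per dataset, large enough for non-trivial joins and
  small enough for sub-second tests. The multi-million-triple scale of
  the real deployments is deliberately not emulated; nothing here
  benchmarks raw speed.
* `rdf:type` and `rdfs:label` in every dataset (the common-predicate
  worst case for index-based selection);
* cross-dataset object links chaining each member to the next (the joins
  federated queries exercise);
* one shared-literal overlap pair — two different predicates in two
  datasets carrying identical literal values, the way a chemistry
  dataset's "title" matches a drug dataset's "genericName" without any
  object link;
* instance IRIs disjoint across datasets, so no triple occurs in two
  members. This is what makes federated-vs-merged comparison an *exact
  multiset* equality: duplicated triples would collapse in the merged
  graph but add up across UNION branches. Real federations do duplicate
  data across mirrors; the engine handles that case by querying only one
  mirror per dataset, and the generator registers true mirrors (same
  graph, different URL, higher latency) for exactly that path.

`worked_example_fixture()` additionally pins the relevance profile of the
classic five-pattern drug query — (1, 1, 1, 1, 2) with two exclusive
groups — by construction. The verbatim predicates of the original query
are stand-ins chosen to reproduce that profile exactly; the acceptance
surface is the relevance-size vector and the block structure, not the IRI
spelling.

A green equivalence suite therefore establishes: the selection, rewriting
and execution machinery is sound on realistic topology at test scale. It
does not establish performance at real scale, robustness to
non-conforming endpoints, or semantics of OPTIONAL across sources beyond
the evaluator's own left-join.

## Query characterization

`compute_features()` reports #BGPs, #TP, total vertices (distinct terms in
any subject/predicate/object position, query-wide), join vertices
(distinct terms in ≥ 2 patterns of the *same* BGP), R = JVs/TVs, mean
join degree, and clause usage. Two conventions deserve note:

* Published benchmark tables truncate the ratio to three decimals
  (2/7 → 0.285); the package computes full precision and offers
  `truncate3()` for display-compatible output. Internally
  `ratio · TVs = JVs` holds exactly.
* Whether a *predicate* repeated across patterns (e.g. `rdf:type` twice)
  counts as a join vertex is not settled by the usual definitions' worked
  examples; the default here follows the literal "subject, predicate or
  object" reading, and `join_positions = "so"` restricts joining to
  subject/object occurrences. A term qualifying in several BGPs counts
  once, with its maximum per-BGP degree.

The shipped `benchmark_query_features()` table records the published
20-query benchmark statistics as input data (its `#TP` column, summed to
139, drives the 10 × 139 = 1390 index-free ASK baseline); one of its rows
is internally inconsistent in the published source (a ratio not matching
its own vertex counts), which is preserved verbatim rather than repaired,
since only `#TP` is consumed.

## Known limitations

* OPTIONAL across SERVICE boundaries: preserved structurally, equivalence
  not guaranteed in corner cases (see above).
* The SPARQL subset excludes property paths, aggregates, subqueries,
  VALUES and named graphs.
* No join reordering, bind joins or semi-join optimization — the rewriter
  targets a competent downstream evaluator.
* No row-level duplicate detection within a dataset, and no detection of
  semantically identical entities under different URIs.
* The HTTP transport is an interface, not an implementation.
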