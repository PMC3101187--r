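---
title: "phylostore: model, mappings, and query semantics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{phylostore: model, mappings, and query semantics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phylostore)
```

## The problem

Phylogenetic results are scattered across incompatible text formats (NEXUS,
nexml, PHYLIP, MEGA, Newick), which capture syntax but not meaning.  The
Comparative Data Analysis Ontology (CDAO) supplies the missing semantic
layer: a vocabulary of classes (Node, Edge, TU, CharacterStateDataMatrix,
EdgeLength, ...) and properties relating them, so that any phylogeny or
character matrix can be expressed as subject--predicate--object *triples*
and queried uniformly.  phylostore implements that idea at desk scale: an
object model mirroring CDAO, readers and writers for the standard formats,
a bidirectional dataset-to-triples mapping with a pattern-queryable store
persisted as N-Triples, a suite of domain queries, and a PhyloWS-style URI
grammar as the service surface.

## The object model and its invariants

A tree is a directed graph of nodes and edges with an optional non-negative
branch length per edge (substitutions/site or arbitrary units).  The
structural invariants are enforced at construction and after every parse,
never assumed: each node has at most one immediate ancestor; the graph is
connected and acyclic, so |edges| = |nodes| − 1; a rooted tree has exactly
one parentless node, its root.  Leaves reference operational taxonomic
units (TUs); unlabeled internal nodes receive synthesized labels
`#node<k>` numbered in parse order, which keeps identifiers reproducible
across round trips.  Polytomies are accepted throughout: nothing in the
model restricts a parent to two children.  Unrooted trees are stored with
an arbitrary anchor node for traversal, but the ancestor-directed
operations (`ancestors_of`, `nearest_common_ancestor`,
`minimum_spanning_clade`, `tree_width`) refuse them rather than guessing a
direction.

A missing branch length is treated as 1.0 wherever a weighted computation
needs a number (`path_length(weighted = TRUE)`, `tree_length`) and is
*omitted* — not written as zero — by every serializer, so absent data is
never invented.

## Format dialects

The readers target the common core of each format and reject what they
cannot interpret rather than silently guessing:

* **NEXUS** — square-bracket comments are stripped anywhere; commands are
  case-insensitive; TAXA, CHARACTERS/DATA (FORMAT
  DATATYPE/MISSING/GAP, sequential or interleaved MATRIX rows) and TREES
  (with TRANSLATE resolution) blocks are interpreted.  Any other block is
  preserved verbatim as an annotation and replayed on export, so no user
  content is dropped by a NEXUS-to-NEXUS round trip.  Declared dimensions
  are checked against the matrix body (`NTAX`/`NCHAR` mismatches error).
* **Newick** — recursive-descent parse with quoted labels (`'...'`, `''`
  escapes) and precise errors for unbalanced parentheses, empty input, and
  trailing garbage.  Output is canonical: children are ordered by the
  smallest leaf label in their subtree, which makes serialization
  deterministic and diffs stable.
* **PHYLIP** — relaxed whitespace-delimited names by default;
  `strict_names = TRUE` selects the classic fixed 10-character field, an
  explicit flag because files in the wild are ambiguous.  Sequential and
  interleaved layouts are both accepted, and the data type is inferred from
  the alphabet (DNA within `{A,C,G,T,U,N,-,?}`, otherwise protein).
* **MEGA** — the sequence-data dialect only (`#mega` header, optional
  `Title`/`Format`/`!` lines, `#Taxon` headers); distance-matrix files are
  rejected with a clear error since they do not map onto a character state
  matrix.
* **nexml** — elements are matched by local name, so namespace version
  drift does not break parsing; cell-based and `<seq>`-based rows are both
  read, and `<state>` tables are dereferenced to symbols.  State symbols
  (including `?` and `-`) are stored verbatim everywhere; no gap/missing
  recoding happens at parse time.

## The triple mapping

`dataset_to_triples()` applies a fixed, testable mapping.  Per tree: one
type triple (`cdao:RootedTree`/`cdao:UnrootedTree`).  Per node: a
`cdao:Node` type triple and a `cdao:belongs_to_Tree` membership triple.
Per leaf: `cdao:represents_TU` plus the TU's type and `rdfs:label`
triples.  Per edge: a type triple (`cdao:DirectedEdge` in rooted trees), a
membership triple, and `cdao:belongs_to_Edge_as_Parent` /
`cdao:belongs_to_Edge_as_Child` triples for its endpoints.  Per measured
branch length: a `cdao:has_Annotation` hub typed `cdao:EdgeLength`
carrying `cdao:has_Value`.  A rooted tree with $V$ nodes, $E$ edges, $L$
leaves and $B$ measured lengths therefore emits exactly

$$1 + 2V + 3L + 4E + 3B$$

tree-derived triples — 36 for the worked `((A,B),C)` example:

```{r}
nrow(dataset_to_triples(as_dataset(parse_newick("((A,B),C);"))))
```

Matrices map per cell: each cell is a skolem subject with
`cdao:belongs_to_TU`, `cdao:belongs_to_Character` and `cdao:has_State`;
characters carry type, matrix membership and a store-local `ps:position`
literal that preserves column order; the matrix carries its type and a
`ps:datatype` literal.  Three design choices are worth stating explicitly:

* **No blank nodes.**  Annotation hubs and cells get deterministic skolem
  IRIs derived from their owners, which makes round trips and triple
  counts exact.
* **No dataset-level type triple.**  Dataset scoping is carried by the IRI
  prefix (`<base>/data/<dataset>/...`), so a one-tree dataset emits exactly
  the count-law triples and nothing else.
* **Internal labels.**  Synthesized `#node<k>` labels are *not* emitted
  (they are renumbered deterministically on reconstruction); an internal
  node with a real name, e.g. a named clade, does get an `rdfs:label`
  triple so the name survives the round trip.

Where CDAO has no term for something the store needs — author, inference
method, software tool, matrix data type, column position — the mapping
uses `dc:creator` and store-local `ps:` terms (`used_method`,
`used_software`, `datatype`, `position`, `has_TU`).  The full table is
returned by `cdao_vocabulary()`.

`triples_to_dataset()` inverts the mapping and validates as it goes: a
dangling edge endpoint, a node without its type triple, or a TU without a
label raises an "incomplete graph" error naming the offending subject.
Matrix *row* order is not asserted in RDF; rows are reconstructed in
natural identifier order, and dataset equality (`dataset_equal`) is
defined up to identifier renaming accordingly.

In place of a SPARQL engine, the store offers a conjunctive
basic-graph-pattern contract: `match_triples()` for single patterns with
wildcards and `match_bgp()` for joined patterns with shared `?variables`.
The searching queries (taxon containment, metadata, data type, statistics)
run on this contract; the structural queries (spanning clades, ancestors,
sizes, distances) run on trees reconstructed from their triples — the same
division of labor as a SPARQL-versus-logic-rules split, chosen because
transitive tree traversal is not a pattern-match problem.

## Query semantics

* **Nearest common ancestor** — the deepest node whose descendant leaf set
  contains all query taxa; taxon labels match exactly after whitespace and
  underscore normalization, and a single taxon resolves to its own leaf.
* **Minimum spanning clade** — the complete subtree rooted at the NCA,
  branch lengths preserved.  Minimality holds by construction: no child of
  the basal node still covers the taxa (asserted against oracles in the
  tests).
* **Size queries** — strict comparisons (`greater`, `less`, `equal`) on a
  criteria of `node`, `internal`, or `leaf`; the three directions
  partition any store for every criteria and threshold.
* **Diameter and width** — both terms are used in practice without a
  standard definition, so this package defines them and tests the
  definitions against brute-force oracles: *diameter* is the maximum
  unweighted path length over all node pairs (computed by the linear
  two-sweep method, verified against all-pairs search), and *width* is the
  maximum number of nodes at any depth level.
* **Robinson–Foulds** — the symmetric difference of the two trees'
  non-trivial bipartition sets.  Bipartitions are computed on the unrooted
  equivalent (a degree-2 root is suppressed) so rooted inputs match
  standard unrooted practice; trees with different leaf sets are an error
  that names the differing taxa.
* **Distance queries** — "at distance q" is read inclusively (≤ q), the
  clustering reading of finding trees *close* to a reference.
  Robinson–Foulds is the topology measure and applies only to trees
  sharing the reference's leaf set; incomparable trees are skipped, not
  errored, because a store-wide filter should not fail on heterogeneous
  content.  Scalar fallbacks (`treelength-diff`, `nodecount-diff`)
  compare across any leaf sets.
* **Statistics** — count, min, max, mean and a histogram of 10 equal-width
  bins spanning [min, max] (one bin when all values coincide), for tree
  length (missing lengths count 1), node count, diameter, or width.
* **Metadata** — case-insensitive substring matching, the usual behavior
  of author search boxes; fields map to `dc:creator`, `ps:used_method`,
  `ps:used_software`.
* Two query families from the original eleven-query characterization —
  relationships among taxa across phylogenies, and model-of-evolution
  search — are intentionally absent, mirroring the "not supported" status
  of their reference implementation: the first was never precisely
  specified, the second requires metadata the model does not carry.

## The URI grammar

Every query is addressable as `/phylows/<type>/<params>` with
`format=`/`limit=`/`offset=` query parameters; `format=rdf` selects
RDF/XML.  Taxon labels containing `/` must be percent-encoded — the
slash-separated taxon list is otherwise ambiguous — and every segment is
decoded before matching.  `render_phylows_uri()` is the exact inverse of
`parse_phylows_uri()`, which makes the grammar testable offline, and
pagination is applied after lexicographic sorting so that pages
concatenate deterministically into the unpaginated result.  The CLI
(`inst/cli/phylostore`) is a thin wrapper over these functions and the
N-Triples persistence; no behavior lives in it.

## The fixture generator

`random_tree()` grows a rooted binary tree by sequential random leaf
attachment: each new leaf splits a uniformly chosen existing edge.  This
was chosen over birth–death or coalescent simulation deliberately —
fixtures need seed-exact determinism and topological variety, not
biological realism — and the generator restores the caller's RNG state.
Branch lengths, when requested, are U(0, 1) rounded to six decimals (which
round-trips exactly through decimal serialization).  What the fixtures do
*not* emulate: realistic branch-length distributions, polytomies (the
generator is binary, though the model accepts polytomies from files),
label collisions, or malformed inputs, which are covered by hand-written
cases instead.  Passing round-trip tests on this corpus therefore
demonstrates structural correctness of the converters, not robustness to
every dialect found in the wild.

## Numerical and scale choices

Branch lengths are serialized with 15 significant digits, enough to
reproduce any double exactly on re-parse.  Statistics means are compared
to direct averaging at 1e-9.  The test and acceptance runs use 200 random
trees of up to 50 leaves for the oracle-equivalence and count-law checks,
100 same-leaf-set pairs of up to 12 leaves plus the exhaustive 15-topology
five-leaf set for Robinson–Foulds, and a 100-dataset corpus for the
round-trip checks — sizes at which the brute-force oracles remain exact
and fast.

## Known limitations

Reticulate networks (child in-degree > 1) are out of scope; the model is
strictly tree-shaped.  NHX extensions, phyloxml *import*, and NEXUS
ASSUMPTIONS/SETS interpretation are not supported (the latter are
preserved opaquely).  phyloxml export covers
phylogeny/clade/name/branch_length only — sufficient for feeding tree
viewers.  The store is single-writer: persistence is a whole-file
canonical N-Triples dump with no transactional concurrency.  Matrix row
order is normalized rather than preserved through the triple mapping, as
described above.
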