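# phylostore

Phylogenetic data as CDAO triples: storage, interconversion, and
domain-specific queries.

Phylogenetic knowledge lives in a zoo of text formats — NEXUS, nexml,
PHYLIP, MEGA, bare Newick — that share no semantics, which makes
cross-study search ("which trees contain these taxa?", "which were built
from DNA?", "which are close to this reference tree?") painful.  The
Comparative Data Analysis Ontology (CDAO) gives trees, taxa, characters
and states a shared vocabulary, so any dataset can be expressed as RDF
triples and queried uniformly.  `phylostore` is a desk-scale
implementation of that stack for people who curate, convert, or mine
collections of phylogenies:

* an object model mirroring CDAO (trees, TUs, character state matrices,
  datasets), with structural invariants validated on every construction
  and parse;
* importers for NEXUS, nexml, PHYLIP, MEGA and Newick, and exporters to
  Newick, NEXUS, nexml, phyloxml, GraphML, Prolog facts, RDF/XML and
  N-Triples — usable as a general format converter (`convert_phylo`);
* a bidirectional mapping between datasets and CDAO-vocabulary triples: a
  rooted tree with *V* nodes, *E* edges, *L* leaves and *B* measured
  branch lengths maps to exactly `1 + 2V + 3L + 4E + 3B` triples, and
  `triples_to_dataset()` inverts the mapping;
* a pattern-queryable triple store (single patterns and conjunctive
  basic graph patterns) persisted as canonically sorted N-Triples;
* the domain query suite: nearest common ancestor, minimum spanning
  clade, taxon containment, author/method/tool metadata, size filters,
  diameter/width properties, Robinson–Foulds distance neighborhoods, and
  measure statistics;
* a PhyloWS-style URI grammar (`/phylows/<querytype>/...`) with a
  deterministic pagination contract, plus a thin command-line front end.

The core comparison statistic is the Robinson–Foulds distance
`RF(T1, T2) = |S(T1) Δ S(T2)|`, the size of the symmetric difference of
the trees' sets of non-trivial bipartitions (leaf splits induced by
internal edges of the unrooted topologies).

## Worked example

```r
library(phylostore)

ds <- parse_phylo_text("((A:1,B:2):0.5,C:1);", "newick", id = "ds1")
st <- store_add_dataset(triple_store(), ds)
st <- annotate_store(st, "ds1", "dc:creator", "W. Piel")
st
#> <triple_store> 49 triples, 1 datasets
```

49 triples = the tree's 48 (here V = 5, E = 4, L = 3, B = 4, so
1 + 10 + 9 + 16 + 12) plus the author annotation.  Querying:

```r
t1 <- store_get_tree(st, "t1")
nearest_common_ancestor(t1, c("A", "B"))
#> [1] "n1"
write_newick(minimum_spanning_clade(t1, c("A", "B"))$clade)
#> [1] "(A:1,B:2);"
tree_diameter(t1); tree_width(t1)
#> [1] 3
#> [1] 2
robinson_foulds(parse_newick("((A,B),(C,D));"), parse_newick("((A,C),(B,D));"))
#> [1] 2
```

`n1` is the internal node joining A and B; its clade is the minimal
subtree containing both query taxa.  The two four-leaf trees disagree on
their single internal split each, hence RF distance 2.  The same queries
are addressable as service URIs:

```r
phylows(st, "/phylows/size/less/leaf/4")$payload
#> [1] "t1"
measure_statistics(st, "treelength")
#> <measure_summary treelength> n=1 min=4.5 mean=4.5 max=4.5
```

And the converter turns any readable format into any writable one:

```r
cat(convert_phylo("2 4\nA ACGT\nB ACGA\n", from = "phylip", to = "nexus"))
#> #NEXUS
#>
#> BEGIN TAXA;
#>   DIMENSIONS NTAX=2;
#>   TAXLABELS A B;
#> END;
#>
#> BEGIN CHARACTERS;
#>   DIMENSIONS NTAX=2 NCHAR=4;
#>   FORMAT DATATYPE=DNA MISSING=? GAP=-;
#>   MATRIX
#>     A ACGT
#>     B ACGA
#>   ;
#> END;
```

A command-line wrapper over the same functions ships in
`inst/cli/phylostore` (import/convert/query/annotate against an N-Triples
store file).

## Package layout

* `R/model.R` — object model, validation, traversal
* `R/newick.R`, `R/nexus.R`, `R/nexml.R`, `R/phylip.R`, `R/mega.R`,
  `R/detect.R` — format readers/writers and the import front door
* `R/triples.R` — CDAO vocabulary, dataset↔triples mapping, pattern
  matching, N-Triples persistence
* `R/queries.R` — the domain query suite
* `R/export.R` — exporters and the converter
* `R/phylows.R` — URI grammar and dispatch
* `R/fixtures.R` — deterministic random trees/matrices and the toy corpus
* `vignettes/phylostore-methods.Rmd` — the methods vignette (model,
  mapping, query semantics, design choices)
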