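Package: phylostore
Title: A CDAO Triple-Store for Phylogenetic Data with Format
    Interconversion and Domain Queries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An object model for phylogenetic trees and character state
    matrices mirroring the Comparative Data Analysis Ontology (CDAO),
    importers for NEXUS, nexml, PHYLIP, MEGA and Newick files, a
    bidirectional mapping between datasets and CDAO-vocabulary RDF
    triples with a pattern-queryable triple store persisted as
    N-Triples, a suite of domain-specific queries (nearest common
    ancestor, minimum spanning clade, taxon containment, metadata,
    size, diameter/width, Robinson-Foulds distance, measure
    statistics, data type), exporters to Newick, NEXUS, nexml,
    phyloxml, GraphML, RDF/XML and Prolog facts, and a PhyloWS-style
    URI grammar with a command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    xml2
Suggests:
    ape,
    igraph,
    optparse,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
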