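# Export of datasets and trees to the supported output formats, and the
# format-to-format converter built from parse -> dataset -> export.

tree_only_formats <- c("newick", "phyloxml", "graphml", "prolog")

first_tree <- function(x, format) {
  if (inherits(x, "cdao_tree")) return(x)
  if (inherits(x, "cdao_dataset")) {
    if (!length(x$trees))
      stop("cannot export to ", format, ": dataset holds no tree ",
           "(matrices are not expressible in a tree-only format)")
    if (length(x$matrices) || length(x$trees) > 1)
      warning("export to ", format, " drops ",
              paste(c(if (length(x$trees) > 1)
                paste(length(x$trees) - 1, "extra tree(s)"),
                if (length(x$matrices))
                  paste(length(x$matrices), "matrix/matrices")),
                collapse = " and "))
    return(x$trees[[1]])
  }
  stop("cannot export object of class ", class(x)[1], " to ", format)
}

as_export_dataset <- function(x) {
  if (inherits(x, "cdao_dataset")) x
  else if (inherits(x, "cdao_tree")) as_dataset(x)
  else if (inherits(x, "cdao_matrix"))
    new_dataset("ds1", tus = x$tus, matrices = list(x))
  else stop("cannot export object of class ", class(x)[1])
}

#' Export a dataset or tree to a phylogenetic format
#'
#' Supported formats: `newick`, `nexus`, `nexml`, `phylip`, `phyloxml`,
#' `graphml`, `prolog`, `rdfxml`, `ntriples`.  Tree-only formats (newick,
#' phyloxml, graphml, prolog) reject matrix-only datasets and warn when a
#' lossy export drops matrices or extra trees.
#'
#' @param x A `cdao_dataset`, `cdao_tree`, or `cdao_matrix`.
#' @param format Output format name.
#' @param base Base IRI for the RDF formats.
#' @return Serialized text.
#' @export
export_phylo <- function(x, format = c("newick", "nexus", "nexml", "phylip",
                                       "phyloxml", "graphml", "prolog",
                                       "rdfxml", "ntriples"),
                         base = DEFAULT_BASE) {
  format <- match.arg(format)
  if (format %in% tree_only_formats) {
    t <- first_tree(x, format)
    return(switch(format,
                  newick = write_newick(t),
                  phyloxml = write_phyloxml(t),
                  graphml = write_graphml(t),
                  prolog = write_prolog(t)))
  }
  ds <- as_export_dataset(x)
  switch(format,
         nexus = write_nexus(ds),
         nexml = write_nexml(ds),
         phylip = {
           if (!length(ds$matrices))
             stop("cannot export to phylip: dataset holds no matrix")
           if (length(ds$trees) || length(ds$matrices) > 1)
             warning("export to phylip keeps only the first matrix")
           write_phylip(ds$matrices[[1]])
         },
         rdfxml = write_rdfxml(dataset_to_triples(ds, base), base),
         ntriples = {
           st <- store_add_dataset(triple_store(base), ds)
           path <- tempfile(fileext = ".nt")
           on.exit(unlink(path))
           save_store(st, path)
           paste(readLines(path), collapse = "\n")
         })
}

#' Convert between phylogenetic file formats
#'
#' Parses the input, passes through the dataset object model, and exports:
#' semantic content (topology, labels, branch lengths, matrix cells) is
#' preserved whenever the target format can express it, and lossy
#' conversions warn about the dropped content.
#'
#' @param text Input file content.
#' @param from Input format, or `"auto"`.
#' @param to Output format (see [export_phylo()]).
#' @return Converted text.
#' @export
convert_phylo <- function(text, from = "auto", to) {
  ds <- parse_phylo_text(text, format = from)
  export_phylo(ds, format = to)
}

# ---- phyloxml ---------------------------------------------------------------

write_phyloxml <- function(tree) {
  doc <- xml2::xml_new_root(
    "phyloxml", xmlns = "http://www.phyloxml.org")
  phy <- xml2::xml_add_child(doc, "phylogeny",
                             rooted = tolower(as.character(isTRUE(tree$rooted))))
  km <- tree_children_map(tree)
  len <- stats::setNames(tree$edges$length, tree$edges$child)
  lab <- stats::setNames(tree$nodes$label, tree$nodes$id)
  anchor <- setdiff(tree$nodes$id, tree$edges$child)
  rec <- function(parent_xml, v) {
    cl <- xml2::xml_add_child(parent_xml, "clade")
    l <- lab[[v]]
    if (!grepl("^#node[0-9]+$", l)) xml2::xml_add_child(cl, "name", l)
    if (!is.na(len[v]))
      xml2::xml_add_child(cl, "branch_length",
                          format(len[v], digits = 15, scientific = FALSE))
    for (k in km[[v]]) rec(cl, k)
  }
  rec(phy, anchor)
  as.character(doc)
}

# ---- GraphML ----------------------------------------------------------------

write_graphml <- function(tree) {
  doc <- xml2::xml_new_root(
    "graphml", xmlns = "http://graphml.graphdrawing.org/xmlns")
  xml2::xml_add_child(doc, "key", id = "label", `for` = "node",
                      attr.name = "label", attr.type = "string")
  xml2::xml_add_child(doc, "key", id = "weight", `for` = "edge",
                      attr.name = "weight", attr.type = "double")
  g <- xml2::xml_add_child(doc, "graph", id = tree$id, edgedefault = "directed")
  for (i in seq_len(nrow(tree$nodes))) {
    nd <- xml2::xml_add_child(g, "node", id = tree$nodes$id[i])
    d <- xml2::xml_add_child(nd, "data", key = "label")
    xml2::xml_text(d) <- tree$nodes$label[i]
  }
  for (i in seq_len(nrow(tree$edges))) {
    e <- tree$edges[i, ]
    # edge labels combine the endpoints as "source_destination"
    ed <- xml2::xml_add_child(g, "edge",
                              id = paste0(e$parent, "_", e$child),
                              source = e$parent, target = e$child)
    if (!is.na(e$length)) {
      d <- xml2::xml_add_child(ed, "data", key = "weight")
      xml2::xml_text(d) <- format(e$length, digits = 15, scientific = FALSE)
    }
  }
  as.character(doc)
}

# ---- Prolog facts -----------------------------------------------------------

pl_atom <- function(x) {
  ifelse(grepl("^[a-z][A-Za-z0-9_]*$", x),
         x, paste0("'", gsub("'", "\\\\'", x), "'"))
}

# ground facts, one per line: tree/1, node/2 (tree, node), edge/4 (tree,
# parent, child, length with 'none' when absent), represents/2 (node, taxon)
write_prolog <- function(tree) {
  leaves <- tree_leaf_ids(tree)
  lab <- stats::setNames(tree$nodes$label, tree$nodes$id)
  lines <- c(
    paste0("tree(", pl_atom(tree$id), ")."),
    paste0("node(", pl_atom(tree$id), ", ", pl_atom(tree$nodes$id), ")."),
    if (nrow(tree$edges))
      paste0("edge(", pl_atom(tree$id), ", ", pl_atom(tree$edges$parent),
             ", ", pl_atom(tree$edges$child), ", ",
             ifelse(is.na(tree$edges$length), "none",
                    format(tree$edges$length, digits = 15,
                           scientific = FALSE)), ")."),
    if (length(leaves))
      paste0("represents(", pl_atom(leaves), ", ",
             pl_atom(unname(lab[leaves])), ").")
  )
  paste(c(lines, ""), collapse = "\n")
}

# ---- RDF/XML ----------------------------------------------------------------

write_rdfxml <- function(triples, base = DEFAULT_BASE) {
  ns <- default_namespaces(base)
  doc <- xml2::xml_new_root("rdf:RDF",
                            "xmlns:rdf" = ns[["rdf"]],
                            "xmlns:rdfs" = ns[["rdfs"]],
                            "xmlns:dc" = ns[["dc"]],
                            "xmlns:cdao" = ns[["cdao"]],
                            "xmlns:ps" = ns[["ps"]])
  qname <- function(iri) {
    for (p in c("rdf", "rdfs", "dc", "cdao", "ps")) {
      if (startsWith(iri, ns[[p]])) {
        local <- substring(iri, nchar(ns[[p]]) + 1L)
        if (grepl("^[A-Za-z_][A-Za-z0-9_.-]*$", local))
          return(paste0(p, ":", local))
      }
    }
    NA_character_
  }
  for (s in unique(triples$subject)) {
    d <- xml2::xml_add_child(doc, "rdf:Description", "rdf:about" = s)
    rows <- triples[triples$subject == s, , drop = FALSE]
    for (i in seq_len(nrow(rows))) {
      qn <- qname(rows$predicate[i])
      if (is.na(qn)) qn <- "ps:property"   # out-of-namespace predicates
      if (rows$otype[i] == "iri") {
        xml2::xml_add_child(d, qn, "rdf:resource" = rows$object[i])
      } else {
        el <- xml2::xml_add_child(d, qn)
        xml2::xml_text(el) <- rows$object[i]
      }
    }
  }
  as.character(doc)
}
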