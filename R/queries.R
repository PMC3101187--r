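# The domain-specific query suite over trees and the triple store.
#
# Mirroring the division of labor between plain repository search and tree
# reasoning, the containment/metadata/datatype/statistics queries run as
# basic-graph-pattern matches against the store, while the structural
# queries (spanning clade, ancestor, size, diameter, width, distance) run on
# trees reconstructed from their triples.

# reconstruct every tree in the store, tagged with its dataset
store_trees <- function(store) {
  out <- list()
  for (ds_id in store_dataset_ids(store)) {
    ds <- triples_to_dataset(store, ds_id)
    for (t in ds$trees)
      out[[length(out) + 1L]] <- list(dataset = ds_id, tree = t)
  }
  out
}

#' Tree identifiers present in a store
#'
#' @param store A `triple_store`.
#' @return Sorted character vector of tree ids.
#' @export
store_tree_ids <- function(store) {
  sort(vapply(store_trees(store), function(x) x$tree$id, ""))
}

#' Fetch one tree from the store by id
#'
#' @param store A `triple_store`.
#' @param tree_id Tree identifier.
#' @return A `cdao_tree`.
#' @export
store_get_tree <- function(store, tree_id) {
  hits <- Filter(function(x) x$tree$id == tree_id, store_trees(store))
  if (!length(hits)) stop("tree '", tree_id, "' not found in store")
  if (length(hits) > 1)
    stop("tree id '", tree_id, "' is ambiguous across datasets")
  hits[[1]]$tree
}

# ---- ancestor / clade queries ----------------------------------------------

#' Nearest common ancestor of a set of taxa
#'
#' The unique deepest node whose descendant leaf set contains every given
#' taxon.  Labels are matched exactly after whitespace/underscore
#' normalization; a single taxon yields its own leaf.
#'
#' @param tree A rooted `cdao_tree`.
#' @param taxa Character vector of taxon labels (at least one).
#' @return Node id of the nearest common ancestor.
#' @export
nearest_common_ancestor <- function(tree, taxa) {
  if (!isTRUE(tree$rooted))
    stop("nearest common ancestor requires a rooted tree")
  if (!length(taxa)) stop("at least one taxon label is required")
  leaf_ids <- tree_leaf_ids(tree)
  labs <- normalize_label(tree$nodes$label)
  node_of <- function(taxon) {
    hit <- tree$nodes$id[labs == normalize_label(taxon)]
    hit <- intersect(hit, leaf_ids)
    if (!length(hit)) stop("taxon '", taxon, "' not found in tree ", tree$id)
    hit[1]
  }
  nodes <- vapply(taxa, node_of, "")
  # intersect root-paths: the nca is the last common element
  paths <- lapply(nodes, function(n) rev(c(n, ancestors_of(tree, n))))
  common <- Reduce(intersect, paths)
  common[length(common)]
}

#' Minimum spanning clade of a set of taxa
#'
#' The smallest clade (a node plus all of its descendants) whose leaf set
#' contains the given taxa: its basal node is the nearest common ancestor,
#' and no child subtree of that node still contains all the taxa.
#'
#' @param tree A rooted `cdao_tree`.
#' @param taxa Character vector of taxon labels.
#' @return List with `basal` (node id) and `clade` (a `cdao_tree`, branch
#'   lengths preserved).
#' @export
minimum_spanning_clade <- function(tree, taxa) {
  basal <- nearest_common_ancestor(tree, taxa)
  keep <- basal
  km <- tree_children_map(tree)
  queue <- basal
  while (length(queue)) {
    v <- queue[[1]]; queue <- queue[-1]
    kids <- km[[v]]
    keep <- c(keep, kids); queue <- c(queue, kids)
  }
  nodes <- tree$nodes[tree$nodes$id %in% keep, , drop = FALSE]
  edges <- tree$edges[tree$edges$parent %in% keep &
                        tree$edges$child %in% keep, , drop = FALSE]
  rownames(nodes) <- rownames(edges) <- NULL
  clade <- structure(list(id = paste0(tree$id, "_msc"), nodes = nodes,
                          edges = edges, rooted = TRUE, root = basal),
                     class = "cdao_tree")
  validate_tree(clade)
  list(basal = basal, clade = clade)
}

# ---- searching queries (over the store) -------------------------------------

# tree IRI -> leaf labels, via one BGP per store
store_tree_leaf_labels <- function(store) {
  b <- match_bgp(store, list(c("?n", "cdao:represents_TU", "?tu"),
                             c("?tu", "rdfs:label", "?lab"),
                             c("?n", "cdao:belongs_to_Tree", "?t")))
  split(b$lab, b$t)
}

iri_tail <- function(iri) dec(sub(".*/", "", iri))

#' Trees containing a given set of taxa
#'
#' @param store A `triple_store`.
#' @param taxa Character vector of taxon labels; refusing an empty list
#'   (rather than returning every tree) keeps the query explicit.
#' @return Character vector of tree ids whose leaf set contains all taxa.
#' @export
trees_containing_taxa <- function(store, taxa) {
  if (!length(taxa)) stop("taxa list must not be empty")
  want <- normalize_label(taxa)
  by_tree <- store_tree_leaf_labels(store)
  hit <- vapply(by_tree, function(labs)
    all(want %in% normalize_label(labs)), TRUE)
  sort(iri_tail(names(by_tree)[hit]))
}

#' Trees selected by dataset metadata
#'
#' Finds trees whose dataset carries a matching annotation: `dc:creator`
#' for authors, `ps:used_method` for inference methods, `ps:used_software`
#' for tools.  Matching is case-insensitive substring.
#'
#' @param store A `triple_store`.
#' @param field One of `"author"`, `"method"`, `"tool"`.
#' @param value Search string.
#' @return Character vector of tree ids.
#' @export
trees_by_metadata <- function(store, field = c("author", "method", "tool"),
                              value) {
  field <- match.arg(field)
  pred <- switch(field, author = "dc:creator", method = "ps:used_method",
                 tool = "ps:used_software")
  hits <- match_triples(store, p = pred)
  hits <- hits[grepl(tolower(value), tolower(hits$object), fixed = TRUE), ,
               drop = FALSE]
  if (!nrow(hits)) return(character(0))
  base <- store$namespaces[["ps"]]
  subj_ds <- function(s) {
    pre <- paste0(base, "data/")
    if (startsWith(s, pre)) sub("/.*$", "", substring(s, nchar(pre) + 1L))
    else NA_character_
  }
  ds_ids <- unique(dec(stats::na.omit(vapply(hits$subject, subj_ds, ""))))
  out <- character(0)
  for (x in store_trees(store)) {
    anno_subjects <- hits$subject
    t_iri <- paste0(dataset_iri(base, x$dataset), "/tree/", enc(x$tree$id))
    if (x$dataset %in% ds_ids || t_iri %in% anno_subjects)
      out <- c(out, x$tree$id)
  }
  sort(unique(out))
}

# ---- size and shape measures ------------------------------------------------

#' Count nodes, internal nodes, or leaves of a tree
#'
#' @param tree A `cdao_tree`.
#' @param criteria `"node"` (all nodes), `"internal"`, or `"leaf"`.
#' @return Integer count.
#' @export
tree_size <- function(tree, criteria = c("node", "internal", "leaf")) {
  criteria <- match.arg(criteria)
  n_leaf <- length(tree_leaf_ids(tree))
  switch(criteria,
         node = nrow(tree$nodes),
         leaf = n_leaf,
         internal = nrow(tree$nodes) - n_leaf)
}

#' Filter store trees by size
#'
#' @param store A `triple_store`.
#' @param direction `"greater"`, `"less"`, or `"equal"` (strict
#'   comparisons).
#' @param criteria Size criteria as in [tree_size()].
#' @param size Non-negative integer.
#' @return Character vector of tree ids.
#' @export
trees_by_size <- function(store, direction = c("greater", "less", "equal"),
                          criteria = c("node", "internal", "leaf"), size) {
  direction <- match.arg(direction); criteria <- match.arg(criteria)
  if (size < 0) stop("size must be non-negative")
  cmp <- switch(direction, greater = `>`, less = `<`, equal = `==`)
  hits <- Filter(function(x) cmp(tree_size(x$tree, criteria), size),
                 store_trees(store))
  sort(vapply(hits, function(x) x$tree$id, ""))
}

#' Tree diameter
#'
#' The maximum unweighted path length (edge count) between any two nodes,
#' computed with the linear two-sweep technique: a farthest node from an
#' arbitrary start is one end of a longest path, and the eccentricity of
#' that end is the diameter.
#'
#' @param tree A `cdao_tree`.
#' @return Integer diameter (0 for a single node).
#' @export
tree_diameter <- function(tree) {
  if (nrow(tree$nodes) == 1) return(0L)
  adj <- c(split(tree$edges$child, factor(tree$edges$parent,
                                          levels = tree$nodes$id)))
  for (i in seq_len(nrow(tree$edges))) {
    adj[[tree$edges$child[i]]] <- c(adj[[tree$edges$child[i]]],
                                    tree$edges$parent[i])
  }
  bfs_far <- function(start) {
    dist <- stats::setNames(rep(NA_integer_, nrow(tree$nodes)),
                            tree$nodes$id)
    dist[start] <- 0L; queue <- start
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      for (w in adj[[v]]) if (is.na(dist[w])) {
        dist[w] <- dist[v] + 1L; queue <- c(queue, w)
      }
    }
    list(node = names(which.max(dist)), dist = max(dist))
  }
  far <- bfs_far(tree$nodes$id[1])
  bfs_far(far$node)$dist
}

#' Tree width
#'
#' The maximum number of nodes found at any single depth level (edge count
#' from the root).
#'
#' @param tree A rooted `cdao_tree`.
#' @return Integer width (1 for a single node).
#' @export
tree_width <- function(tree) {
  if (!isTRUE(tree$rooted)) stop("tree width requires a rooted tree")
  max(table(node_depths(tree)))
}

#' Filter store trees by a computed property
#'
#' @param store A `triple_store`.
#' @param property `"diameter"` or `"width"`.
#' @param value Integer the property must equal.
#' @return Character vector of tree ids.
#' @export
trees_by_property <- function(store, property = c("diameter", "width"),
                              value) {
  property <- match.arg(property)
  f <- switch(property, diameter = tree_diameter, width = tree_width)
  hits <- Filter(function(x) f(x$tree) == value, store_trees(store))
  sort(vapply(hits, function(x) x$tree$id, ""))
}

# ---- Robinson-Foulds distance -----------------------------------------------

# non-trivial bipartitions of the unrooted equivalent of a tree, as
# canonical strings; a degree-2 root is suppressed first so rooted trees
# match standard unrooted practice
tree_bipartitions <- function(tree) {
  leaves <- sort(tree_leaf_labels(tree))
  n <- length(leaves)
  km <- tree_children_map(tree)
  anchor <- setdiff(tree$nodes$id, tree$edges$child)
  below <- new.env(parent = emptyenv())
  fill <- function(v) {
    kids <- km[[v]]
    labs <- if (!length(kids)) tree$nodes$label[tree$nodes$id == v]
    else unlist(lapply(kids, fill))
    assign(v, labs, envir = below)
    labs
  }
  fill(anchor)
  canon <- function(labs) {
    other <- setdiff(leaves, labs)
    if (length(labs) < 2 || length(other) < 2) return(NA_character_)
    side <- if (leaves[1] %in% labs) other else labs
    paste(sort(side), collapse = "\r")
  }
  internal_children <- setdiff(tree$edges$child, tree_leaf_ids(tree))
  # edges into children of a suppressed root merge into one unrooted edge;
  # both children give the same split so duplicates fall out of the set
  splits <- vapply(internal_children,
                   function(v) canon(get(v, envir = below)), "")
  unique(splits[!is.na(splits)])
}

#' Robinson-Foulds distance between two trees
#'
#' The size of the symmetric difference of the two trees' sets of
#' non-trivial bipartitions (the leaf-set splits induced by internal edges
#' of the unrooted topologies).  Both trees must carry the same leaf label
#' set.
#'
#' @param t1,t2 `cdao_tree` objects over the same leaves.
#' @return Non-negative integer; 0 iff the unrooted topologies agree.
#' @export
robinson_foulds <- function(t1, t2) {
  l1 <- sort(normalize_label(tree_leaf_labels(t1)))
  l2 <- sort(normalize_label(tree_leaf_labels(t2)))
  if (!identical(l1, l2)) {
    d <- union(setdiff(l1, l2), setdiff(l2, l1))
    stop("leaf sets differ (", paste(d, collapse = ", "),
         "); Robinson-Foulds is defined on a common leaf set")
  }
  b1 <- tree_bipartitions(t1); b2 <- tree_bipartitions(t2)
  length(setdiff(b1, b2)) + length(setdiff(b2, b1))
}

#' Total branch length of a tree
#'
#' Sum of branch lengths over all edges; an absent length counts as 1.
#'
#' @param tree A `cdao_tree`.
#' @return Non-negative number.
#' @export
tree_length <- function(tree) {
  len <- tree$edges$length
  len[is.na(len)] <- 1
  sum(len)
}

#' Trees within a distance of a reference tree
#'
#' Returns every other tree `t` with `distance(ref, t) <= q`.  The
#' topological measure `"rf"` (Robinson-Foulds) applies to trees sharing
#' the reference's leaf set — trees with incomparable leaf sets are skipped,
#' not errored.  The scalar measures `"treelength-diff"` and
#' `"nodecount-diff"` (absolute differences) compare all trees.
#'
#' @param store A `triple_store`.
#' @param ref Tree id of the reference.
#' @param m Measure: `"rf"`, `"treelength-diff"`, or `"nodecount-diff"`.
#' @param q Non-negative distance threshold.
#' @return Character vector of tree ids.
#' @export
trees_within_distance <- function(store, ref,
                                  m = c("rf", "treelength-diff",
                                        "nodecount-diff"), q) {
  m <- match.arg(m)
  ref_tree <- store_get_tree(store, ref)
  out <- character(0)
  for (x in store_trees(store)) {
    t <- x$tree
    if (t$id == ref) next
    d <- switch(m,
                rf = {
                  same <- setequal(normalize_label(tree_leaf_labels(t)),
                                   normalize_label(tree_leaf_labels(ref_tree)))
                  if (!same) NA_real_ else robinson_foulds(ref_tree, t)
                },
                `treelength-diff` = abs(tree_length(ref_tree) - tree_length(t)),
                `nodecount-diff` = abs(nrow(ref_tree$nodes) - nrow(t$nodes)))
    if (!is.na(d) && d <= q) out <- c(out, t$id)
  }
  sort(unique(out))
}

# ---- statistics -------------------------------------------------------------

#' Distribution of a measure over all store trees
#'
#' Computes count, min, max, mean and a 10-equal-width-bin histogram of a
#' per-tree measure across the store (a single bin when all values
#' coincide).
#'
#' @param store A non-empty `triple_store`.
#' @param m Measure: `"treelength"`, `"nodecount"`, `"diameter"`, or
#'   `"width"`.
#' @return A `measure_summary`: list with `measure`, `count`, `min`, `max`,
#'   `mean`, and `histogram` (data frame `bin_low`, `bin_high`, `count`).
#' @export
measure_statistics <- function(store, m = c("treelength", "nodecount",
                                            "diameter", "width")) {
  m <- match.arg(m)
  trees <- store_trees(store)
  if (!length(trees)) stop("store holds no trees")
  f <- switch(m, treelength = tree_length,
              nodecount = function(t) nrow(t$nodes),
              diameter = tree_diameter, width = tree_width)
  vals <- vapply(trees, function(x) as.numeric(f(x$tree)), 0)
  lo <- min(vals); hi <- max(vals)
  if (lo == hi) {
    hist <- data.frame(bin_low = lo, bin_high = hi, count = length(vals))
  } else {
    breaks <- seq(lo, hi, length.out = 11L)
    idx <- pmin(findInterval(vals, breaks, rightmost.closed = TRUE), 10L)
    hist <- data.frame(bin_low = breaks[1:10], bin_high = breaks[2:11],
                       count = as.integer(tabulate(idx, nbins = 10L)))
  }
  structure(list(measure = m, count = length(vals), min = lo, max = hi,
                 mean = mean(vals), histogram = hist),
            class = "measure_summary")
}

#' @export
print.measure_summary <- function(x, ...) {
  cat(sprintf("<measure_summary %s> n=%d min=%g mean=%g max=%g\n",
              x$measure, x$count, x$min, x$mean, x$max))
  invisible(x)
}

#' Trees built from a given data type
#'
#' Trees belonging to a dataset that contains a character matrix of the
#' given data type; optionally intersected with a taxon-containment query.
#'
#' @param store A `triple_store`.
#' @param datatype One of `"DNA"`, `"RNA"`, `"protein"`, `"standard"`,
#'   `"continuous"`.
#' @param taxa Optional taxon labels the trees must also contain.
#' @return Character vector of tree ids.
#' @export
trees_by_datatype <- function(store,
                              datatype = c("DNA", "RNA", "protein",
                                           "standard", "continuous"),
                              taxa = NULL) {
  datatype <- match.arg(datatype)
  hits <- match_triples(store, p = "ps:datatype")
  hits <- hits$subject[hits$object == datatype]
  base <- store$namespaces[["ps"]]
  pre <- paste0(base, "data/")
  ds_ids <- unique(dec(sub("/.*$", "",
                           substring(hits[startsWith(hits, pre)],
                                     nchar(pre) + 1L))))
  out <- character(0)
  for (x in store_trees(store))
    if (x$dataset %in% ds_ids) out <- c(out, x$tree$id)
  out <- sort(unique(out))
  if (!is.null(taxa) && length(taxa))
    out <- intersect(out, trees_containing_taxa(store, taxa))
  out
}
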