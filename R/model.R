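#' phylostore: phylogenetic data as CDAO triples
#'
#' An object model for phylogenies and character state matrices that mirrors
#' the Comparative Data Analysis Ontology (CDAO), readers and writers for the
#' standard phylogenetic file formats, a bidirectional mapping to an RDF
#' triple store, a suite of domain-specific queries, and a PhyloWS-style URI
#' grammar tying them together.
#'
#' @section Object model:
#' Trees are directed rooted graphs of [Node][build_tree] records joined by
#' edges with optional non-negative branch lengths; leaves point at
#' operational taxonomic units (TUs).  Character matrices are TU-by-character
#' tables of state symbols with a data type tag.  A dataset bundles TUs,
#' trees, matrices and annotations.
#'
#' @keywords internal
"_PACKAGE"

# ---- constructors -----------------------------------------------------------

new_tu <- function(id, label) {
  stopifnot(is.character(id), is.character(label))
  if (any(!nzchar(label))) stop("TU labels must be non-empty")
  data.frame(id = id, label = label, stringsAsFactors = FALSE)
}

#' Create a character matrix object
#'
#' Builds a TU-by-character state matrix in the CDAO sense: rows are
#' operational taxonomic units, columns are characters, and each cell holds a
#' state symbol (`"A"`, `"0"`, `"?"`, `"-"`, or a numeric string for
#' continuous data).  Missing cells are allowed.
#'
#' @param id Matrix identifier.
#' @param tus Data frame with columns `id`, `label`: the ordered row TUs.
#' @param characters Data frame with columns `id`, `label`: the ordered
#'   columns.
#' @param cells Data frame with columns `tu_ref`, `character_ref`, `state`.
#' @param datatype One of `"DNA"`, `"RNA"`, `"protein"`, `"standard"`,
#'   `"continuous"`.
#' @return An object of class `cdao_matrix`.
#' @export
new_character_matrix <- function(id, tus, characters, cells,
                                 datatype = c("DNA", "RNA", "protein",
                                              "standard", "continuous")) {
  datatype <- match.arg(datatype)
  m <- structure(list(id = id, tus = tus, characters = characters,
                      cells = cells, datatype = datatype),
                 class = "cdao_matrix")
  validate_matrix(m)
  m
}

validate_matrix <- function(m) {
  stopifnot(inherits(m, "cdao_matrix"))
  bad_tu <- setdiff(m$cells$tu_ref, m$tus$id)
  if (length(bad_tu)) stop("cells reference unknown TU: ", bad_tu[1])
  bad_ch <- setdiff(m$cells$character_ref, m$characters$id)
  if (length(bad_ch)) stop("cells reference unknown character: ", bad_ch[1])
  key <- paste(m$cells$tu_ref, m$cells$character_ref)
  if (anyDuplicated(key)) stop("duplicate (TU, character) cell in matrix ", m$id)
  invisible(m)
}

#' Bundle trees, matrices, TUs and annotations into a dataset
#'
#' A dataset is the unit of import/export and of triple mapping: every
#' cross-reference (leaf to TU, cell to TU and character) must resolve within
#' it.  Annotations are subject/predicate/value records whose predicate is a
#' namespaced term (e.g. `dc:creator`).
#'
#' @param id Dataset identifier.
#' @param tus Data frame with columns `id`, `label`.
#' @param trees List of `cdao_tree` objects.
#' @param matrices List of `cdao_matrix` objects.
#' @param annotations Data frame with columns `subject`, `predicate`,
#'   `value`, or `NULL`.
#' @return An object of class `cdao_dataset`.
#' @export
new_dataset <- function(id, tus = NULL, trees = list(), matrices = list(),
                        annotations = NULL) {
  if (is.null(tus)) tus <- new_tu(character(), character())
  if (is.null(annotations))
    annotations <- data.frame(subject = character(), predicate = character(),
                              value = character(), stringsAsFactors = FALSE)
  names(trees) <- vapply(trees, function(t) t$id, "")
  names(matrices) <- vapply(matrices, function(m) m$id, "")
  ds <- structure(list(id = id, tus = tus, trees = trees,
                       matrices = matrices, annotations = annotations),
                  class = "cdao_dataset")
  validate_dataset(ds)
  ds
}

validate_dataset <- function(ds) {
  stopifnot(inherits(ds, "cdao_dataset"))
  if (anyDuplicated(ds$tus$id)) stop("duplicate TU id in dataset ", ds$id)
  for (t in ds$trees) {
    validate_tree(t)
    refs <- t$nodes$tu_ref[!is.na(t$nodes$tu_ref)]
    bad <- setdiff(refs, ds$tus$id)
    if (length(bad)) stop("tree ", t$id, " references unknown TU: ", bad[1])
  }
  for (m in ds$matrices) {
    validate_matrix(m)
    bad <- setdiff(m$tus$id, ds$tus$id)
    if (length(bad)) stop("matrix ", m$id, " references unknown TU: ", bad[1])
  }
  if (nrow(ds$annotations) &&
      any(!grepl(":", ds$annotations$predicate, fixed = TRUE)))
    stop("annotation predicates must be namespaced terms")
  invisible(ds)
}

#' Wrap a single tree as a dataset
#'
#' Synthesizes one TU per leaf label so the tree can be mapped to triples or
#' exported to matrix-capable formats.
#'
#' @param tree A `cdao_tree`.
#' @param id Dataset identifier.
#' @return A `cdao_dataset` holding the tree.
#' @export
as_dataset <- function(tree, id = "ds1") {
  stopifnot(inherits(tree, "cdao_tree"))
  leaf <- tree$nodes[!is.na(tree$nodes$tu_ref), , drop = FALSE]
  new_dataset(id, tus = new_tu(leaf$tu_ref, leaf$label), trees = list(tree))
}

# ---- tree construction ------------------------------------------------------

#' Build a validated tree from a parent/child edge list
#'
#' Nodes are synthesized from the labels in first-appearance order.  Leaves
#' (labels never appearing as a parent) are linked to synthesized TU ids;
#' internal nodes keep their label.  The structural invariants of a
#' phylogeny are enforced: every node has at most one immediate ancestor, the
#' graph is connected and acyclic, and a rooted tree has exactly one
#' parentless node, its root.
#'
#' @param edges List of vectors/lists `(parent, child)` or
#'   `(parent, child, length)`; labels are strings, lengths non-negative
#'   numbers.
#' @param rooted Logical; rooted trees support ancestor-directed queries.
#' @param id Tree identifier.
#' @return An object of class `cdao_tree` with components `id`, `nodes`
#'   (data frame `id`, `label`, `tu_ref`), `edges` (data frame `id`,
#'   `parent`, `child`, `length`), `rooted`, `root`.
#' @examples
#' t <- build_tree(list(c("r", "x"), c("x", "A"), c("x", "B"), c("r", "C")))
#' tree_size(t, "leaf")
#' @export
build_tree <- function(edges, rooted = TRUE, id = "t1") {
  if (!length(edges)) stop("edge list must be non-empty")
  par <- vapply(edges, function(e) as.character(e[[1]]), "")
  chi <- vapply(edges, function(e) as.character(e[[2]]), "")
  len <- vapply(edges, function(e)
    if (length(e) >= 3 && !is.na(e[[3]])) as.numeric(e[[3]]) else NA_real_, 0)
  labels <- unique(c(rbind(par, chi)))
  node_id <- paste0("n", seq_along(labels))
  names(node_id) <- labels
  is_leaf <- !(labels %in% par)
  tu_ref <- ifelse(is_leaf, paste0("tu", cumsum(is_leaf)), NA_character_)
  nodes <- data.frame(id = unname(node_id), label = labels, tu_ref = tu_ref,
                      stringsAsFactors = FALSE)
  edf <- data.frame(id = paste0("e", seq_along(par)),
                    parent = unname(node_id[par]),
                    child = unname(node_id[chi]),
                    length = len, stringsAsFactors = FALSE)
  root <- NA_character_
  if (rooted) {
    parentless <- setdiff(nodes$id, edf$child)
    if (length(parentless) != 1)
      stop("rooted tree must have exactly one parentless node, found ",
           length(parentless))
    root <- parentless
  }
  t <- structure(list(id = id, nodes = nodes, edges = edf,
                      rooted = rooted, root = root),
                 class = "cdao_tree")
  validate_tree(t)
  t
}

#' Check the structural invariants of a tree
#'
#' Verifies child in-degree at most 1, endpoint existence, parent != child,
#' non-negative branch lengths, |edges| = |nodes| - 1, connectedness and
#' acyclicity, and (when rooted) a unique parentless root.
#'
#' @param tree A `cdao_tree`.
#' @return The tree, invisibly; errors describe the violated invariant.
#' @export
validate_tree <- function(tree) {
  stopifnot(inherits(tree, "cdao_tree"))
  n <- tree$nodes; e <- tree$edges
  if (anyDuplicated(n$id)) stop("duplicate node id")
  if (nrow(e)) {
    bad <- setdiff(c(e$parent, e$child), n$id)
    if (length(bad)) stop("edge references unknown node: ", bad[1])
    if (any(e$parent == e$child)) stop("self-loop edge (parent equals child)")
    dup <- e$child[duplicated(e$child)]
    if (length(dup))
      stop("node ", n$label[match(dup[1], n$id)],
           " has two parents (child in-degree > 1)")
    if (any(!is.na(e$length) & e$length < 0))
      stop("negative branch length")
  }
  if (nrow(e) != nrow(n) - 1)
    stop("tree is disconnected or cyclic: |edges| != |nodes| - 1")
  # reachability from the parentless node(s) catches cycles and disconnection
  parentless <- setdiff(n$id, e$child)
  if (!length(parentless)) stop("cycle: no parentless node")
  kids <- split(e$child, factor(e$parent, levels = n$id))
  seen <- character(0); queue <- parentless
  while (length(queue)) {
    v <- queue[[1]]; queue <- queue[-1]
    seen <- c(seen, v)
    queue <- c(queue, kids[[v]])
  }
  if (length(seen) != nrow(n)) stop("tree is disconnected or contains a cycle")
  if (isTRUE(tree$rooted)) {
    if (length(parentless) != 1 || !identical(tree$root, parentless))
      stop("rooted tree must have its unique parentless node as root")
  }
  invisible(tree)
}

# ---- traversal helpers ------------------------------------------------------

# named vector: child id -> parent id
tree_parent_map <- function(tree) {
  stats::setNames(tree$edges$parent, tree$edges$child)
}

# list: parent id -> character vector of child ids (in edge order)
tree_children_map <- function(tree) {
  split(tree$edges$child, factor(tree$edges$parent, levels = tree$nodes$id))
}

tree_leaf_ids <- function(tree) {
  setdiff(tree$nodes$id, tree$edges$parent)
}

#' Leaf labels of a tree
#'
#' @param tree A `cdao_tree`.
#' @return Character vector of the TU labels at the leaves.
#' @export
tree_leaf_labels <- function(tree) {
  tree$nodes$label[tree$nodes$id %in% tree_leaf_ids(tree)]
}

node_depths <- function(tree) {
  pm <- tree_parent_map(tree)
  depth <- stats::setNames(rep(NA_real_, nrow(tree$nodes)), tree$nodes$id)
  anchor <- setdiff(tree$nodes$id, tree$edges$child)
  depth[anchor] <- 0
  km <- tree_children_map(tree)
  queue <- anchor
  while (length(queue)) {
    v <- queue[[1]]; queue <- queue[-1]
    for (c in km[[v]]) {
      depth[c] <- depth[v] + 1
      queue <- c(queue, c)
    }
  }
  depth
}

resolve_node <- function(tree, node) {
  if (node %in% tree$nodes$id) return(node)
  hit <- tree$nodes$id[tree$nodes$label == node]
  if (length(hit) == 1) return(hit)
  stop("unknown node '", node, "' in tree ", tree$id)
}

#' Ancestors of a node, nearest first
#'
#' Walks the unique parent chain from `node` to the root.  Internal nodes are
#' the common ancestors of the leaves below them, so this path underlies the
#' nearest-common-ancestor and spanning-clade queries.
#'
#' @param tree A rooted `cdao_tree`.
#' @param node Node id (or unique node label).
#' @return Character vector of node ids from the node's parent up to the
#'   root; empty for the root itself.
#' @export
ancestors_of <- function(tree, node) {
  if (!isTRUE(tree$rooted)) stop("ancestors_of requires a rooted tree")
  node <- resolve_node(tree, node)
  pm <- tree_parent_map(tree)
  out <- character(0)
  while (!is.na(pm[node])) {
    node <- unname(pm[node])
    out <- c(out, node)
  }
  out
}

#' Taxon labels of the leaves descending from a node
#'
#' @param tree A rooted `cdao_tree`.
#' @param node Node id (or unique label); a leaf yields itself.
#' @return Character vector of TU labels (a set; order follows traversal).
#' @export
leaves_under <- function(tree, node) {
  if (!isTRUE(tree$rooted)) stop("leaves_under requires a rooted tree")
  node <- resolve_node(tree, node)
  km <- tree_children_map(tree)
  leaves <- tree_leaf_ids(tree)
  out <- character(0); queue <- node
  while (length(queue)) {
    v <- queue[[1]]; queue <- queue[-1]
    if (v %in% leaves) out <- c(out, v)
    queue <- c(queue, km[[v]])
  }
  tree$nodes$label[match(out, tree$nodes$id)]
}

#' Path length between two nodes
#'
#' Length of the unique undirected path between two nodes: the edge count, or
#' with `weighted = TRUE` the sum of branch lengths along it (an absent
#' length counts as 1, substitutions/site or arbitrary units).
#'
#' @param tree A `cdao_tree`.
#' @param a,b Node ids (or unique labels).
#' @param weighted Sum branch lengths instead of counting edges.
#' @return Non-negative number.
#' @export
path_length <- function(tree, a, b, weighted = FALSE) {
  a <- resolve_node(tree, a); b <- resolve_node(tree, b)
  if (a == b) return(0)
  pm <- tree_parent_map(tree)
  wt <- tree$edges$length
  wt[is.na(wt)] <- 1
  ewt <- stats::setNames(wt, tree$edges$child)   # edge keyed by its child node
  up_path <- function(x) {
    ids <- x; while (!is.na(pm[x])) { x <- unname(pm[x]); ids <- c(ids, x) }
    ids
  }
  pa <- up_path(a); pb <- up_path(b)
  meet <- pa[pa %in% pb][1]          # first shared ancestor, nearest to a
  seg <- c(pa[seq_len(match(meet, pa) - 1)], pb[seq_len(match(meet, pb) - 1)])
  if (weighted) sum(ewt[seg]) else length(seg)
}

#' @export
print.cdao_tree <- function(x, ...) {
  cat(sprintf("<cdao_tree %s> %d nodes, %d edges, %s\n", x$id,
              nrow(x$nodes), nrow(x$edges),
              if (isTRUE(x$rooted)) paste0("rooted at ", x$root) else "unrooted"))
  lv <- tree_leaf_labels(x)
  cat("  leaves:", paste(utils::head(lv, 8), collapse = ", "),
      if (length(lv) > 8) "..." else "", "\n")
  invisible(x)
}

#' @export
print.cdao_dataset <- function(x, ...) {
  cat(sprintf("<cdao_dataset %s> %d TUs, %d trees, %d matrices, %d annotations\n",
              x$id, nrow(x$tus), length(x$trees), length(x$matrices),
              nrow(x$annotations)))
  invisible(x)
}

#' @export
print.cdao_matrix <- function(x, ...) {
  cat(sprintf("<cdao_matrix %s> %d TUs x %d characters (%s), %d cells\n",
              x$id, nrow(x$tus), nrow(x$characters), x$datatype,
              nrow(x$cells)))
  invisible(x)
}

# taxa matching rule shared by the query engine: exact after trimming and
# treating underscores as spaces
normalize_label <- function(x) {
  gsub("\\s+", " ", trimws(gsub("_", " ", x)))
}
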