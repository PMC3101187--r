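# Independent brute-force oracles used to check the package's tree
# algorithms.  They work directly on the nodes/edges data frames and never
# call the traversal helpers they are meant to verify.

# undirected adjacency list
oracle_adj <- function(tree) {
  adj <- stats::setNames(vector("list", nrow(tree$nodes)), tree$nodes$id)
  for (i in seq_len(nrow(tree$edges))) {
    p <- tree$edges$parent[i]; c <- tree$edges$child[i]
    adj[[p]] <- c(adj[[p]], c)
    adj[[c]] <- c(adj[[c]], p)
  }
  adj
}

# breadth-first distances from one node
oracle_bfs <- function(tree, start) {
  adj <- oracle_adj(tree)
  dist <- stats::setNames(rep(NA_integer_, nrow(tree$nodes)), tree$nodes$id)
  dist[start] <- 0L; queue <- start
  while (length(queue)) {
    v <- queue[[1]]; queue <- queue[-1]
    for (w in adj[[v]]) if (is.na(dist[w])) {
      dist[w] <- dist[v] + 1L
      queue <- c(queue, w)
    }
  }
  dist
}

oracle_path_length <- function(tree, a, b) unname(oracle_bfs(tree, a)[b])

# all-pairs diameter
oracle_diameter <- function(tree) {
  max(vapply(tree$nodes$id, function(v) max(oracle_bfs(tree, v)), 0L))
}

# depth of each node by repeated parent lookups in the edge table
oracle_depths <- function(tree) {
  vapply(tree$nodes$id, function(v) {
    d <- 0L
    repeat {
      i <- which(tree$edges$child == v)
      if (!length(i)) return(d)
      v <- tree$edges$parent[i]; d <- d + 1L
    }
  }, 0L)
}

oracle_width <- function(tree) max(table(oracle_depths(tree)))

# leaf labels reachable from a node following child edges only
oracle_leafset <- function(tree, node) {
  stack <- node; out <- character(0)
  while (length(stack)) {
    v <- stack[[1]]; stack <- stack[-1]
    kids <- tree$edges$child[tree$edges$parent == v]
    if (!length(kids)) out <- c(out, tree$nodes$label[tree$nodes$id == v])
    stack <- c(stack, kids)
  }
  out
}

# deepest node whose leaf set contains all the taxa, by scanning every node
oracle_nca <- function(tree, taxa) {
  depths <- oracle_depths(tree)
  cand <- tree$nodes$id[vapply(tree$nodes$id, function(v)
    all(taxa %in% oracle_leafset(tree, v)), TRUE)]
  cand[which.max(depths[match(cand, tree$nodes$id)])]
}

# non-trivial bipartitions by deleting each edge and splitting the leaves
# into the two connected components of what remains
oracle_splits <- function(tree) {
  leaves <- sort(tree$nodes$label[!tree$nodes$id %in% tree$edges$parent])
  out <- character(0)
  for (i in seq_len(nrow(tree$edges))) {
    rest <- tree$edges[-i, , drop = FALSE]
    comp <- tree$edges$child[i]   # component containing the child endpoint
    repeat {
      grow <- unique(c(rest$child[rest$parent %in% comp],
                       rest$parent[rest$child %in% comp]))
      grow <- setdiff(grow, comp)
      if (!length(grow)) break
      comp <- c(comp, grow)
    }
    side <- sort(intersect(tree$nodes$label[match(comp, tree$nodes$id)],
                           leaves))
    other <- setdiff(leaves, side)
    if (length(side) < 2 || length(other) < 2) next
    if (leaves[1] %in% side) side <- other
    out <- c(out, paste(side, collapse = "|"))
  }
  unique(out)
}

oracle_rf <- function(t1, t2) {
  s1 <- oracle_splits(t1); s2 <- oracle_splits(t2)
  length(setdiff(s1, s2)) + length(setdiff(s2, s1))
}

# every rooted binary labeled topology on the given leaves (used at n = 5
# to enumerate the 15 unrooted shapes after deduplication by split set)
enumerate_rooted <- function(leaves) {
  if (length(leaves) == 1) return(list(leaves))
  out <- list()
  rest <- leaves[-1]
  for (k in seq_len(length(rest))) {
    for (left_rest in combn_list(rest, k - 1L)) {
      left <- c(leaves[1], left_rest)
      right <- setdiff(leaves, left)
      if (!length(right)) next
      for (lt in enumerate_rooted(left))
        for (rt in enumerate_rooted(right))
          out[[length(out) + 1L]] <- list(lt, rt)
    }
  }
  out
}

combn_list <- function(x, k) {
  if (k == 0) return(list(character(0)))
  if (k > length(x)) return(list())
  apply(utils::combn(x, k), 2, identity, simplify = FALSE)
}

shape_to_newick <- function(s) {
  rec <- function(x) {
    if (is.character(x)) x
    else paste0("(", rec(x[[1]]), ",", rec(x[[2]]), ")")
  }
  paste0(rec(s), ";")
}

# the 15 distinct unrooted 5-leaf topologies, as rooted representatives
all_five_leaf_topologies <- function() {
  trees <- lapply(enumerate_rooted(c("A", "B", "C", "D", "E")),
                  function(s) parse_newick(shape_to_newick(s)))
  sig <- vapply(trees, function(t)
    paste(sort(oracle_splits(t)), collapse = ";"), "")
  trees[!duplicated(sig)]
}

# random dataset corpus used by the round-trip checks: tree-only,
# matrix-only, and mixed datasets, annotation-free
fixture_corpus <- function(n, seed = 42L) {
  lapply(seq_len(n), function(i) {
    s <- seed + i
    kind <- i %% 4L
    id <- paste0("ds", i)
    if (kind %in% c(0L, 1L)) {
      t <- random_tree(2L + (i %% 25L), seed = s,
                       branch_lengths = if (i %% 2L) "uniform" else "none")
      as_dataset(t, id)
    } else if (kind == 2L) {
      m <- random_matrix(2L + (i %% 6L), 3L + (i %% 8L), seed = s,
                         alphabet = c("DNA", "protein", "standard")[1L + (i %% 3L)])
      new_dataset(id, tus = m$tus, matrices = list(m))
    } else {
      t <- random_tree(3L + (i %% 10L), seed = s, branch_lengths = "uniform")
      leaf <- t$nodes[!is.na(t$nodes$tu_ref), ]
      m <- random_matrix(nrow(leaf), 4L, seed = s + 1000L)
      # align the matrix rows with the tree's TUs
      m$tus <- data.frame(id = leaf$tu_ref, label = leaf$label,
                          stringsAsFactors = FALSE)
      m$cells$tu_ref <- leaf$tu_ref[match(m$cells$tu_ref,
                                          paste0("tu", seq_len(nrow(leaf))))]
      new_dataset(id, tus = new_tu(leaf$tu_ref, leaf$label),
                  trees = list(t), matrices = list(m))
    }
  })
}

to_ape <- function(tree) ape::read.tree(text = write_newick(tree))

resolve_node_label <- function(tree, label) {
  tree$nodes$id[tree$nodes$label == label][1]
}

new_query_spec_for_test <- function(...) phylostore:::new_query_spec(...)

# memoized per-node leaf sets in one bottom-up pass (fast oracle variant
# used where the brute-force scan is run over hundreds of trees)
oracle_leafsets_all <- function(tree) {
  depth <- oracle_depths(tree)
  sets <- stats::setNames(vector("list", nrow(tree$nodes)), tree$nodes$id)
  for (v in tree$nodes$id[order(depth, decreasing = TRUE)]) {
    kids <- tree$edges$child[tree$edges$parent == v]
    sets[[v]] <- if (!length(kids))
      tree$nodes$label[tree$nodes$id == v]
    else unlist(sets[kids], use.names = FALSE)
  }
  sets
}

oracle_nca_fast <- function(tree, taxa, sets = oracle_leafsets_all(tree),
                            depth = oracle_depths(tree)) {
  cand <- tree$nodes$id[vapply(sets, function(s) all(taxa %in% s), TRUE)]
  cand[which.max(depth[match(cand, tree$nodes$id)])]
}

# all-pairs shortest paths through igraph, as an external distance oracle
oracle_distances_igraph <- function(tree) {
  g <- igraph::graph_from_data_frame(
    tree$edges[, c("parent", "child")], directed = FALSE,
    vertices = tree$nodes$id)
  igraph::distances(g)
}

# cells keyed by (row label, column position) -> state, id-independent
matrix_cells_by_label <- function(m) {
  pos <- match(m$cells$character_ref, m$characters$id)
  row <- m$tus$label[match(m$cells$tu_ref, m$tus$id)]
  sort(paste(row, pos, m$cells$state, sep = "/"))
}
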