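# Deterministic random fixtures: every module is testable without any
# external download.  The global RNG state is saved and restored, so fixture
# generation never perturbs a caller's random stream.

with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_old) assign(".Random.seed", old, envir = globalenv())
          else rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Generate a random rooted binary tree
#'
#' Builds the tree by sequential random leaf attachment: starting from a
#' two-leaf cherry, each new leaf splits a uniformly chosen existing edge
#' (or, with equal chance among attachment points, the root edge position).
#' Output is identical for identical `(n_leaves, seed)`; leaves are labeled
#' `T1..Tn`.
#'
#' @param n_leaves Number of leaves (>= 1).
#' @param seed Integer seed.
#' @param branch_lengths `"none"` or `"uniform"` (lengths drawn from
#'   U(0, 1), rounded to 6 digits).
#' @param id Tree identifier.
#' @return A `cdao_tree`.
#' @export
random_tree <- function(n_leaves, seed = 1L,
                        branch_lengths = c("none", "uniform"), id = "t1") {
  branch_lengths <- match.arg(branch_lengths)
  stopifnot(n_leaves >= 1)
  if (n_leaves == 1) {
    nodes <- data.frame(id = "n1", label = "T1", tu_ref = "tu1",
                        stringsAsFactors = FALSE)
    return(structure(list(id = id, nodes = nodes,
                          edges = data.frame(id = character(),
                                             parent = character(),
                                             child = character(),
                                             length = numeric(),
                                             stringsAsFactors = FALSE),
                          rooted = TRUE, root = "n1"),
                     class = "cdao_tree"))
  }
  with_seed(seed, {
    # edges as (parent-label, child-label); internal labels #node<k>
    k <- 1L
    edges <- list(c("#node1", "T1"), c("#node1", "T2"))
    for (leaf in seq(3L, length.out = n_leaves - 2L)) {
      i <- sample.int(length(edges), 1L)
      k <- k + 1L
      split_edge <- edges[[i]]
      new_int <- paste0("#node", k)
      edges[[i]] <- c(split_edge[1], new_int)
      edges[[length(edges) + 1L]] <- c(new_int, split_edge[2])
      edges[[length(edges) + 1L]] <- c(new_int, paste0("T", leaf))
    }
    if (branch_lengths == "uniform")
      edges <- lapply(edges, function(e)
        c(e, round(stats::runif(1), 6)))
    build_tree(edges, rooted = TRUE, id = id)
  })
}

#' Generate a random fully-filled character matrix
#'
#' States are drawn uniformly from the alphabet of the chosen data type
#' (`DNA`: ACGT; `protein`: the 20 amino-acid letters; `standard`: 01).
#'
#' @param n_taxa,n_chars Dimensions (>= 1).
#' @param seed Integer seed.
#' @param alphabet `"DNA"`, `"protein"`, or `"standard"`.
#' @param id Matrix identifier.
#' @return A `cdao_matrix` with `n_taxa * n_chars` cells.
#' @export
random_matrix <- function(n_taxa, n_chars, seed = 1L,
                          alphabet = c("DNA", "protein", "standard"),
                          id = "m1") {
  alphabet <- match.arg(alphabet)
  stopifnot(n_taxa >= 1, n_chars >= 1)
  states <- switch(alphabet,
                   DNA = c("A", "C", "G", "T"),
                   protein = strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                   standard = c("0", "1"))
  with_seed(seed, {
    rows <- stats::setNames(
      lapply(seq_len(n_taxa), function(i)
        paste(sample(states, n_chars, replace = TRUE), collapse = "")),
      paste0("T", seq_len(n_taxa)))
    counter <- 0L
    build_matrix_from_rows(rows, id,
                           datatype = if (alphabet == "protein") "protein"
                           else if (alphabet == "DNA") "DNA" else "standard",
                           tu_id_for = function(label) {
                             counter <<- counter + 1L
                             paste0("tu", counter)
                           })
  })
}

#' The built-in toy corpus
#'
#' The worked examples used throughout the documentation and tests: the
#' `((A,B),C)` tree expressed in every input format, the 2x4 DNA matrix in
#' each matrix format, and the four-leaf pair whose Robinson-Foulds
#' distance is 2.  Each entry carries the raw text, its format, and the
#' expected parse.
#'
#' @return List of entries, each `list(name, format, text, expected)` where
#'   `expected` is a `cdao_dataset`.
#' @export
toy_corpus <- function() {
  tree_abc <- function(id = "t1")
    build_tree(list(c("#node2", "#node1"), c("#node1", "A"),
                    c("#node1", "B"), c("#node2", "C")),
               rooted = TRUE, id = id)
  mat24 <- function() {
    counter <- 0L
    build_matrix_from_rows(list(A = "ACGT", B = "ACGA"), "m1", "DNA",
                           function(label) {
                             counter <<- counter + 1L
                             paste0("tu", counter)
                           })
  }
  ds_tree <- as_dataset(tree_abc())
  ds_mat <- local({
    m <- mat24()
    new_dataset("ds1", tus = m$tus, matrices = list(m))
  })
  nexml_tree <- paste0(
    '<nexml xmlns="http://www.nexml.org/2009" version="0.9">',
    '<otus id="otus1"><otu id="tu1" label="A"/><otu id="tu2" label="B"/>',
    '<otu id="tu3" label="C"/></otus>',
    '<trees id="trees1" otus="otus1"><tree id="t1">',
    '<node id="n1" root="true"/><node id="n2"/>',
    '<node id="n3" otu="tu1"/><node id="n4" otu="tu2"/>',
    '<node id="n5" otu="tu3"/>',
    '<edge id="e1" source="n1" target="n2"/>',
    '<edge id="e2" source="n2" target="n3"/>',
    '<edge id="e3" source="n2" target="n4"/>',
    '<edge id="e4" source="n1" target="n5"/>',
    '</tree></trees></nexml>')
  list(
    list(name = "tree_newick", format = "newick",
         text = "((A,B),C);", expected = ds_tree),
    list(name = "tree_nexus", format = "nexus",
         text = paste("#NEXUS", "BEGIN TAXA;",
                      "  DIMENSIONS NTAX=3;", "  TAXLABELS A B C;", "END;",
                      "BEGIN TREES;", "  TREE t1 = ((A,B),C);", "END;",
                      sep = "\n"),
         expected = ds_tree),
    list(name = "tree_nexus_translate", format = "nexus",
         text = paste("#NEXUS", "BEGIN TREES;",
                      "  TRANSLATE 1 A, 2 B, 3 C;",
                      "  TREE t1 = ((1,2),3);", "END;", sep = "\n"),
         expected = ds_tree),
    list(name = "tree_nexml", format = "nexml",
         text = nexml_tree, expected = ds_tree),
    list(name = "matrix_phylip", format = "phylip",
         text = "2 4\nA ACGT\nB ACGA\n", expected = ds_mat),
    list(name = "matrix_phylip_interleaved", format = "phylip",
         text = "2 8\nA ACGT\nB ACGA\n\nTTTT\nGGGG\n",
         expected = local({
           counter <- 0L
           m <- build_matrix_from_rows(list(A = "ACGTTTTT", B = "ACGAGGGG"),
                                       "m1", "DNA",
                                       function(label) {
                                         counter <<- counter + 1L
                                         paste0("tu", counter)
                                       })
           new_dataset("ds1", tus = m$tus, matrices = list(m))
         })),
    list(name = "matrix_mega", format = "mega",
         text = "#mega\n#A\nACGT\n#B\nACGA\n", expected = ds_mat),
    list(name = "matrix_nexus", format = "nexus",
         text = paste("#NEXUS", "BEGIN DATA;",
                      "  DIMENSIONS NTAX=2 NCHAR=4;",
                      "  FORMAT DATATYPE=DNA MISSING=? GAP=-;",
                      "  MATRIX", "    A ACGT", "    B ACGA", "  ;", "END;",
                      sep = "\n"),
         expected = ds_mat),
    list(name = "rf_pair_left", format = "newick",
         text = "((A,B),(C,D));",
         expected = as_dataset(parse_newick("((A,B),(C,D));"))),
    list(name = "rf_pair_right", format = "newick",
         text = "((A,C),(B,D));",
         expected = as_dataset(parse_newick("((A,C),(B,D));")))
  )
}
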