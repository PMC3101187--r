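toy_store <- function() {
  st <- triple_store()
  st <- store_add_dataset(st, as_dataset(parse_newick("((A,B),C);"), "d1"))
  st <- store_add_dataset(st, as_dataset(parse_newick("((B,C),D);", id = "t2"),
                                         "d2"))
  st <- store_add_dataset(st,
                          as_dataset(parse_newick("((A,B),(C,D));", id = "t3"),
                                     "d3"))
  st
}

test_that("nearest common ancestor resolves single taxa, pairs, and errors", {
  t <- parse_newick("((A,B),C);")
  x <- t$edges$parent[t$edges$child == resolve_node_label(t, "A")]
  expect_equal(nearest_common_ancestor(t, c("A", "B")), x)
  expect_equal(nearest_common_ancestor(t, c("A", "C")), t$root)
  expect_equal(nearest_common_ancestor(t, "A"), resolve_node_label(t, "A"))
  expect_error(nearest_common_ancestor(t, c("A", "Z")), "Z")
  expect_error(nearest_common_ancestor(t, character(0)), "at least one")
  u <- t; u$rooted <- FALSE
  expect_error(nearest_common_ancestor(u, "A"), "rooted")
})

test_that("nca matches the brute-force deepest-covering-node oracle", {
  for (i in 1:40) {
    t <- random_tree(3 + (i %% 30), seed = 500 + i)
    leaves <- tree_leaf_labels(t)
    taxa <- sample(leaves, min(length(leaves), 1 + (i %% 4)))
    expect_equal(nearest_common_ancestor(t, taxa), oracle_nca(t, taxa))
  }
})

test_that("minimum spanning clade is the subtree at the nca, and minimal", {
  t <- parse_newick("((A,B),C);")
  res <- minimum_spanning_clade(t, c("A", "B"))
  expect_equal(res$basal, nearest_common_ancestor(t, c("A", "B")))
  expect_equal(nrow(res$clade$nodes), 3)
  expect_equal(nrow(res$clade$edges), 2)
  expect_setequal(tree_leaf_labels(res$clade), c("A", "B"))
  expect_equal(write_newick(minimum_spanning_clade(t, c("A", "B", "C"))$clade),
               write_newick(t))
  single <- minimum_spanning_clade(t, "A")
  expect_equal(nrow(single$clade$nodes), 1)
  # minimality: no child of the basal node still covers the taxa, and
  # branch lengths are preserved
  tw <- parse_newick("(((A:1,B:2):1,C:3):1,D:4);")
  resw <- minimum_spanning_clade(tw, c("A", "C"))
  kids <- tw$edges$child[tw$edges$parent == resw$basal]
  for (k in kids)
    expect_false(all(c("A", "C") %in% leaves_under(tw, k)))
  expect_true(all(resw$clade$edges$length %in% tw$edges$length))
})

test_that("taxon containment queries use exact normalized matching", {
  st <- toy_store()
  expect_setequal(trees_containing_taxa(st, c("B", "C")),
                  c("t1", "t2", "t3"))
  expect_setequal(trees_containing_taxa(st, c("A", "D")), "t3")
  expect_equal(trees_containing_taxa(st, "Z"), character(0))
  expect_error(trees_containing_taxa(st, character(0)), "empty")
  # underscore and space forms match each other
  st2 <- store_add_dataset(triple_store(),
                           as_dataset(parse_newick("(Homo_sapiens,Pan);"),
                                      "d9"))
  expect_equal(trees_containing_taxa(st2, "Homo sapiens"), "t1")
})

test_that("metadata queries match case-insensitive substrings per field", {
  st <- toy_store()
  st <- annotate_store(st, "d1", "dc:creator", "W. Piel")
  st <- annotate_store(st, "d2", "ps:used_method", "Maximum Parsimony")
  st <- annotate_store(st, "d2", "ps:used_software", "PAUP*")
  expect_equal(trees_by_metadata(st, "author", "piel"), "t1")
  expect_equal(trees_by_metadata(st, "method", "parsimony"), "t2")
  expect_equal(trees_by_metadata(st, "tool", "paup"), "t2")
  expect_equal(trees_by_metadata(st, "method", "likelihood"), character(0))
  expect_error(trees_by_metadata(st, "year", "2011"))
})

test_that("tree_size counts nodes, internals, and leaves", {
  t <- parse_newick("((A,B),C);")
  expect_equal(tree_size(t, "node"), 5)
  expect_equal(tree_size(t, "internal"), 2)
  expect_equal(tree_size(t, "leaf"), 3)
  t1 <- random_tree(1, seed = 1)
  expect_equal(tree_size(t1, "node"), 1)
  expect_equal(tree_size(t1, "internal"), 0)
  expect_equal(tree_size(t1, "leaf"), 1)
  expect_equal(tree_size(parse_newick("((A,B),(C,D));"), "node"), 7)
})

test_that("size queries compare strictly and partition the store", {
  st <- toy_store()
  expect_setequal(trees_by_size(st, "less", "leaf", 4), c("t1", "t2"))
  expect_setequal(trees_by_size(st, "equal", "leaf", 4), "t3")
  expect_equal(trees_by_size(st, "greater", "leaf", 10), character(0))
  expect_error(trees_by_size(st, "less", "leaf", -1), "non-negative")
  all_ids <- store_tree_ids(st)
  for (crit in c("node", "internal", "leaf")) {
    for (n in 0:8) {
      parts <- list(trees_by_size(st, "greater", crit, n),
                    trees_by_size(st, "less", crit, n),
                    trees_by_size(st, "equal", crit, n))
      expect_setequal(unlist(parts), all_ids)
      expect_equal(sum(lengths(parts)), length(all_ids))
    }
  }
})

test_that("diameter and width match their brute-force oracles", {
  expect_equal(tree_diameter(parse_newick("((A,B),C);")), 3)
  expect_equal(tree_diameter(parse_newick("((A,B),(C,D));")), 4)
  expect_equal(tree_diameter(random_tree(1, seed = 1)), 0)
  expect_equal(tree_width(parse_newick("((A,B),(C,D));")), 4)
  expect_equal(tree_width(parse_newick("((A,B),C);")), 2)
  expect_equal(tree_width(random_tree(1, seed = 1)), 1)
  for (i in 1:40) {
    t <- random_tree(2 + (i %% 25), seed = 600 + i)
    expect_equal(tree_diameter(t), oracle_diameter(t))
    expect_equal(unname(tree_width(t)), unname(oracle_width(t)))
  }
})

test_that("property queries filter on computed diameter and width", {
  st <- toy_store()
  expect_setequal(trees_by_property(st, "diameter", 3), c("t1", "t2"))
  expect_equal(trees_by_property(st, "width", 4), "t3")
  expect_error(trees_by_property(st, "depth", 3))
})

test_that("robinson_foulds matches exhaustive bipartition enumeration", {
  t1 <- parse_newick("((A,B),(C,D));")
  t2 <- parse_newick("((A,C),(B,D));")
  expect_equal(robinson_foulds(t1, t2), 2)
  expect_equal(robinson_foulds(t1, t1), 0)
  expect_error(robinson_foulds(t1, parse_newick("((A,B),C);")),
               "leaf sets differ")
  for (i in 1:30) {
    n <- 4 + (i %% 9)
    a <- random_tree(n, seed = 700 + i)
    b <- random_tree(n, seed = 800 + i)
    expect_equal(robinson_foulds(a, b), oracle_rf(a, b))
  }
})

test_that("robinson_foulds agrees with the phangorn reference", {
  skip_if_not_installed("phangorn")
  for (i in 1:20) {
    n <- 4 + (i %% 10)
    a <- random_tree(n, seed = 900 + i)
    b <- random_tree(n, seed = 950 + i)
    expect_equal(robinson_foulds(a, b),
                 as.numeric(phangorn::RF.dist(to_ape(a), to_ape(b))))
  }
})

test_that("rf is a pseudometric on the 15 five-leaf topologies", {
  tops <- all_five_leaf_topologies()
  n <- length(tops)
  d <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) d[i, j] <- robinson_foulds(tops[[i]],
                                                           tops[[j]])
  expect_true(all(d == t(d)))
  expect_true(all(diag(d) == 0))
  expect_true(all(d[upper.tri(d)] > 0))   # distinct topologies
  for (i in 1:n) for (j in 1:n) for (k in 1:n)
    expect_true(d[i, k] <= d[i, j] + d[j, k])
})

test_that("distance queries honor the threshold and skip incomparable trees", {
  st <- toy_store()
  expect_equal(trees_within_distance(st, "t1", "rf", 0), character(0))
  st2 <- store_add_dataset(st,
                           as_dataset(parse_newick("(C,(B,A));", id = "t4"),
                                      "d4"))
  expect_equal(trees_within_distance(st2, "t1", "rf", 0), "t4")
  # nodecount-diff: t1 has 5 nodes; within 2 of 5 is 3..7
  expect_setequal(trees_within_distance(st2, "t1", "nodecount-diff", 2),
                  c("t2", "t3", "t4"))
  # unweighted edges count 1 each: treelengths are t1=4, t2=4, t3=6, t4=4
  expect_setequal(trees_within_distance(st2, "t1", "treelength-diff", 2),
                  c("t2", "t3", "t4"))
  expect_error(trees_within_distance(st, "zz", "rf", 1), "not found")
})

test_that("measure statistics summarize the whole store", {
  st <- triple_store()
  st <- store_add_dataset(st, as_dataset(parse_newick("((A:1,B:2):0.5,C:1);"),
                                         "d1"))
  st <- store_add_dataset(st, as_dataset(parse_newick("(X:1,Y:1);", id = "t2"),
                                         "d2"))
  s <- measure_statistics(st, "treelength")
  expect_equal(s$count, 2)
  expect_equal(s$min, 2)
  expect_equal(s$max, 4.5)
  expect_equal(s$mean, 3.25)
  expect_equal(sum(s$histogram$count), s$count)
  one <- measure_statistics(store_add_dataset(triple_store(),
                                              as_dataset(parse_newick("(A,B);"),
                                                         "d1")),
                            "nodecount")
  expect_equal(one$count, 1)
  expect_equal(one$min, one$max)
  expect_equal(one$min, one$mean)
  expect_equal(nrow(one$histogram), 1)
  expect_error(measure_statistics(triple_store(), "nodecount"), "no trees")
  st3 <- toy_store()
  s3 <- measure_statistics(st3, "nodecount")
  expect_equal(s3$mean, mean(c(5, 5, 7)), tolerance = 1e-12)
})

test_that("datatype queries join matrices to their dataset's trees", {
  t <- parse_newick("((A,B),C);")
  leaf <- t$nodes[!is.na(t$nodes$tu_ref), ]
  m <- random_matrix(3, 4, seed = 3)
  m$tus <- data.frame(id = leaf$tu_ref, label = leaf$label,
                      stringsAsFactors = FALSE)
  m$cells$tu_ref <- leaf$tu_ref[match(m$cells$tu_ref, paste0("tu", 1:3))]
  ds <- new_dataset("d1", tus = new_tu(leaf$tu_ref, leaf$label),
                    trees = list(t), matrices = list(m))
  st <- store_add_dataset(triple_store(), ds)
  expect_equal(trees_by_datatype(st, "DNA"), "t1")
  expect_equal(trees_by_datatype(st, "protein"), character(0))
  expect_equal(trees_by_datatype(st, "DNA", taxa = "Z"), character(0))
  expect_equal(trees_by_datatype(st, "DNA", taxa = c("A", "B")), "t1")
})
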