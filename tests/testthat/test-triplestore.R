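test_that("the toy tree maps to exactly its mapping-table triple count", {
  ds <- as_dataset(parse_newick("((A,B),C);"))
  tr <- dataset_to_triples(ds)
  expect_equal(nrow(tr), 36)   # 1 + 2*5 + 3*3 + 4*4
  dsl <- as_dataset(parse_newick("((A:1,B:2):0.5,C:1);"))
  expect_equal(nrow(dataset_to_triples(dsl)), 48)   # 36 + 3*4
  empty <- new_dataset("e")
  expect_equal(nrow(dataset_to_triples(empty)), 0)
})

test_that("triple counts follow 1 + 2V + 3L + 4E + 3B on random trees", {
  for (i in 1:50) {
    t <- random_tree(2 + (i %% 20), seed = 400 + i,
                     branch_lengths = if (i %% 2) "uniform" else "none")
    tr <- dataset_to_triples(as_dataset(t))
    V <- nrow(t$nodes); E <- nrow(t$edges)
    L <- length(tree_leaf_labels(t)); B <- sum(!is.na(t$edges$length))
    expect_equal(nrow(tr), 1 + 2 * V + 3 * L + 4 * E + 3 * B)
  }
})

test_that("datasets survive the round trip through triples", {
  corpus <- fixture_corpus(20, seed = 7)
  st <- triple_store()
  for (ds in corpus) st <- store_add_dataset(st, ds)
  for (ds in corpus) {
    back <- triples_to_dataset(st, ds$id)
    expect_true(dataset_equal(ds, back), label = ds$id)
  }
})

test_that("distinct topologies stay distinct through the triple mapping", {
  tops <- all_five_leaf_topologies()
  expect_length(tops, 15)
  seen <- character(0)
  for (t in tops) {
    back <- triples_to_dataset(store_add_dataset(triple_store(),
                                                 as_dataset(t)), "ds1")
    nwk <- write_newick(back$trees[[1]])
    expect_equal(nwk, write_newick(t))
    seen <- c(seen, paste(sort(oracle_splits(back$trees[[1]])),
                          collapse = ";"))
  }
  expect_length(unique(seen), 15)
})

test_that("incomplete graphs are rejected with the offending subject", {
  st <- store_add_dataset(triple_store(),
                          as_dataset(parse_newick("((A,B),C);")))
  voc_node <- "http://purl.obolibrary.org/obo/cdao.owl#Node"
  drop <- which(st$triples$object == voc_node)[1]
  st$triples <- st$triples[-drop, ]
  expect_error(triples_to_dataset(st, "ds1"), "incomplete graph")
})

test_that("pattern matching unifies wildcards and conjunctive patterns", {
  st <- store_add_dataset(triple_store(),
                          as_dataset(parse_newick("((A,B),C);")))
  expect_equal(nrow(match_triples(st, p = "rdf:type", o = "cdao:Node")), 5)
  expect_equal(nrow(match_triples(st)), 36)
  expect_equal(nrow(match_triples(st, s = "http://nowhere.example/x")), 0)
  b <- match_bgp(st, list(c("?n", "cdao:represents_TU", "?tu"),
                          c("?tu", "rdfs:label", "?lab")))
  expect_setequal(b$lab, c("A", "B", "C"))
  # unions distribute over match
  st2 <- store_add_dataset(st, as_dataset(parse_newick("(X,Y);", id = "t2"),
                                          "ds2"))
  m1 <- match_triples(st, p = "rdf:type", o = "cdao:Node")$subject
  m2 <- match_triples(store_add_dataset(triple_store(),
                                        as_dataset(parse_newick("(X,Y);",
                                                                id = "t2"),
                                                   "ds2")),
                      p = "rdf:type", o = "cdao:Node")$subject
  expect_setequal(match_triples(st2, p = "rdf:type", o = "cdao:Node")$subject,
                  union(m1, m2))
})

test_that("annotation is namespaced, additive, and idempotent", {
  st <- store_add_dataset(triple_store(),
                          as_dataset(parse_newick("((A,B),C);")))
  n0 <- nrow(st$triples)
  st <- annotate_store(st, "ds1", "dc:creator", "W. Piel")
  expect_equal(nrow(st$triples), n0 + 1)
  st <- annotate_store(st, "ds1", "dc:creator", "W. Piel")
  expect_equal(nrow(st$triples), n0 + 1)
  expect_error(annotate_store(st, "ds1", "creator", "x"), "namespaced")
})

test_that("N-Triples persistence is canonical and invertible", {
  st <- store_add_dataset(triple_store(),
                          as_dataset(parse_newick("((A:1,B:2):0.5,C:1);")))
  st <- annotate_store(st, "ds1", "dc:creator", 'quote " and\nnewline')
  f1 <- withr::local_tempfile(fileext = ".nt")
  f2 <- withr::local_tempfile(fileext = ".nt")
  save_store(st, f1)
  back <- load_store(f1)
  expect_setequal(paste(st$triples$subject, st$triples$predicate,
                        st$triples$object, st$triples$otype),
                  paste(back$triples$subject, back$triples$predicate,
                        back$triples$object, back$triples$otype))
  save_store(back, f2)
  expect_identical(readLines(f1), readLines(f2))
  # empty store round trip
  f3 <- withr::local_tempfile(fileext = ".nt")
  save_store(triple_store(), f3)
  expect_equal(nrow(load_store(f3)$triples), 0)
  writeLines("<a> <b> <c>", f3)   # missing terminal dot
  expect_error(load_store(f3), "line 1")
})
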