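test_that("detect_format applies the stated rules", {
  expect_equal(detect_format("#NEXUS\nBEGIN TAXA; END;"), "nexus")
  expect_equal(detect_format("#mega\n#A\nACGT"), "mega")
  expect_equal(detect_format("2 4\nA ACGT\nB ACGA"), "phylip")
  expect_equal(detect_format("((A,B),C);"), "newick")
  expect_equal(detect_format('<nexml xmlns="http://www.nexml.org/2009"/>'),
               "nexml")
  expect_equal(detect_format(paste0('<rdf:RDF xmlns:rdf=',
                                    '"http://www.w3.org/1999/02/22-rdf-syntax-ns#"/>')),
               "rdfxml")
  expect_equal(detect_format("<s> <p> <o> ."), "ntriples")
  expect_error(detect_format("hello world"), "unknown format")
  expect_error(detect_format("  "), "empty")
})

test_that("parse_newick handles labels, lengths, and quoting", {
  t <- parse_newick("((A,B),C);")
  expect_equal(nrow(t$nodes), 5)
  expect_equal(nrow(t$edges), 4)
  expect_setequal(tree_leaf_labels(t), c("A", "B", "C"))
  tw <- parse_newick("((A:1,B:2):0.5,C:1);")
  expect_equal(sum(tw$edges$length), 4.5)
  tq <- parse_newick("(('Ilex anomala':2,'don''t':1),C);")
  expect_true("Ilex anomala" %in% tree_leaf_labels(tq))
  expect_true("don't" %in% tree_leaf_labels(tq))
  # internal labels synthesized in parse order
  expect_true(all(grepl("^#node[0-9]+$",
                        t$nodes$label[is.na(t$nodes$tu_ref)])))
})

test_that("parse_newick rejects malformed strings", {
  expect_error(parse_newick("((A,B,C);"), "expected|unbalanced")
  expect_error(parse_newick(""), "empty")
  expect_error(parse_newick("((A,B),C); junk"), "trailing")
  expect_error(parse_newick("(A,B)"), "expected ';'")
})

test_that("newick parses agree with the ape reference parser", {
  skip_if_not_installed("ape")
  for (i in 1:20) {
    t <- random_tree(3 + (i %% 15), seed = 300 + i,
                     branch_lengths = "uniform")
    nwk <- write_newick(t)
    ref <- ape::read.tree(text = nwk)
    expect_equal(sort(ref$tip.label), sort(tree_leaf_labels(t)))
    expect_equal(ref$Nnode + length(ref$tip.label), nrow(t$nodes))
    expect_equal(sort(ref$edge.length), sort(t$edges$length))
  }
})

test_that("parse_nexus reads taxa, trees, and matrices", {
  ds <- parse_nexus(paste("#NEXUS",
                          "BEGIN TAXA; DIMENSIONS NTAX=3; TAXLABELS A B C; END;",
                          "BEGIN TREES; TREE t1 = ((A,B),C); END;",
                          sep = "\n"))
  expect_equal(nrow(ds$tus), 3)
  expect_length(ds$trees, 1)
  expect_length(ds$matrices, 0)
  ds2 <- parse_nexus(paste("#NEXUS", "BEGIN DATA;",
                           "DIMENSIONS NTAX=2 NCHAR=4;",
                           "FORMAT DATATYPE=DNA MISSING=? GAP=-;",
                           "MATRIX", "A ACGT", "B ACGA", ";", "END;",
                           sep = "\n"))
  m <- ds2$matrices[[1]]
  expect_equal(nrow(m$cells), 8)
  expect_equal(m$datatype, "DNA")
  expect_error(parse_nexus(paste("#NEXUS", "BEGIN DATA;",
                                 "DIMENSIONS NTAX=3 NCHAR=4;",
                                 "MATRIX", "A ACGT", "B ACGA", ";", "END;",
                                 sep = "\n")),
               "NTAX")
  expect_error(parse_nexus("BEGIN TAXA; END;"), "#NEXUS")
})

test_that("nexus TRANSLATE tables resolve leaf labels", {
  ds <- parse_nexus(paste("#NEXUS", "BEGIN TREES;",
                          "TRANSLATE 1 Homo_sapiens, 2 Pan, 3 Gorilla;",
                          "TREE t1 = ((1,2),3);", "END;", sep = "\n"))
  expect_setequal(tree_leaf_labels(ds$trees[[1]]),
                  c("Homo_sapiens", "Pan", "Gorilla"))
  expect_error(parse_nexus(paste("#NEXUS", "BEGIN TREES;",
                                 "TRANSLATE 1 A, 2 B;",
                                 "TREE t1 = ((1,2),3);", "END;", sep = "\n")),
               "TRANSLATE")
})

test_that("nexus comments are stripped and odd blocks preserved", {
  ds <- parse_nexus(paste("#NEXUS [a comment]",
                          "BEGIN TAXA; TAXLABELS A B [why not] C; END;",
                          "BEGIN ASSUMPTIONS; USERTYPE x = 1; END;",
                          sep = "\n"))
  expect_equal(nrow(ds$tus), 3)
  expect_true(any(ds$annotations$predicate == "ps:nexus_block"))
  # preserved blocks survive a NEXUS round trip
  ds2 <- parse_nexus(write_nexus(ds))
  expect_true(any(grepl("ASSUMPTIONS", ds2$annotations$value)))
})

test_that("parse_nexml mirrors the newick parse of the same topology", {
  entry <- Filter(function(e) e$name == "tree_nexml", toy_corpus())[[1]]
  ds <- parse_nexml(entry$text)
  expect_equal(nrow(ds$tus), 3)
  expect_equal(write_newick(ds$trees[[1]]),
               write_newick(parse_newick("((A,B),C);")))
  expect_error(parse_nexml(sub('target="n3"', 'target="n9"', entry$text)),
               "undeclared node")
  expect_error(parse_nexml(sub('otu="tu1"', 'otu="zz"', entry$text)),
               "undeclared otu")
})

test_that("phylip sequential and interleaved layouts agree", {
  seq_m <- parse_phylip("2 8\nA ACGTTTTT\nB ACGAGGGG\n")
  int_m <- parse_phylip("2 8\nA ACGT\nB ACGA\n\nTTTT\nGGGG\n")
  expect_true(dataset_equal(
    new_dataset("x", tus = seq_m$tus, matrices = list(seq_m)),
    new_dataset("y", tus = int_m$tus, matrices = list(int_m))))
  expect_equal(nrow(parse_phylip("2 4\nA ACGT\nB ACGA\n")$cells), 8)
  expect_equal(parse_phylip("2 4\nA ACGT\nB ACGA\n")$datatype, "DNA")
  expect_equal(parse_phylip("2 4\nA MKVL\nB MKVI\n")$datatype, "protein")
  expect_error(parse_phylip("3 4\nA ACGT\nB ACGA\n"), "declared 3 taxa")
  expect_error(parse_phylip("2 6\nA ACGT\nB ACGA\n"), "nchar")
  m <- parse_phylip("2 4\nTaxonNameXACGT\nTaxonNameYACGA\n",
                    strict_names = TRUE)
  expect_setequal(m$tus$label, c("TaxonNameX", "TaxonNameY"))
})

test_that("mega files parse to the same matrix as their phylip twin", {
  ds <- parse_mega("#mega\n#A\nACGT\n#B\nACGA\n")
  m <- parse_phylip("2 4\nA ACGT\nB ACGA\n")
  expect_true(dataset_equal(ds, new_dataset("x", tus = m$tus,
                                            matrices = list(m))))
  expect_error(parse_mega("#mega\n#A\nACGT\n#B\nACGAA\n"), "inconsistent")
  expect_error(parse_mega("#mega\n"), "no taxa")
  expect_error(parse_mega("ACGT"), "begin with")
  expect_error(parse_mega("#mega\n!Format datatype=distance;\n"), "distance")
})

test_that("the toy corpus parses to its expected datasets in every format", {
  for (e in toy_corpus()) {
    ds <- parse_phylo_text(e$text, e$format)
    expect_true(dataset_equal(ds, e$expected), label = e$name)
    expect_equal(detect_format(e$text), e$format)
  }
})

test_that("all tree formats yield the same dataset for the toy tree", {
  entries <- Filter(function(e) startsWith(e$name, "tree_"), toy_corpus())
  parsed <- lapply(entries, function(e) parse_phylo_text(e$text, e$format))
  for (i in seq_along(parsed)[-1])
    expect_true(dataset_equal(parsed[[1]], parsed[[i]]),
                label = entries[[i]]$name)
  mats <- Filter(function(e) e$name %in%
                   c("matrix_phylip", "matrix_mega", "matrix_nexus"),
                 toy_corpus())
  pm <- lapply(mats, function(e) parse_phylo_text(e$text, e$format))
  for (i in seq_along(pm)[-1])
    expect_true(dataset_equal(pm[[1]], pm[[i]]), label = mats[[i]]$name)
})
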