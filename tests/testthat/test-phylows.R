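ws_store <- function() {
  st <- triple_store()
  st <- store_add_dataset(st, as_dataset(parse_newick("((A,B),C);"), "d1"))
  st <- store_add_dataset(st, as_dataset(parse_newick("((B,C),D);", id = "t2"),
                                         "d2"))
  st <- store_add_dataset(st,
                          as_dataset(parse_newick("((A,B),(C,D));", id = "t3"),
                                     "d3"))
  st
}

test_that("the canonical tree-fetch URI parses as documented", {
  s <- parse_phylows_uri("/phylows/tree/TB2:Tr3099?format=rdf")
  expect_s3_class(s, "query_spec")
  expect_equal(s$qtype, "tree")
  expect_equal(s$target_id, "TB2:Tr3099")
  expect_equal(s$format, "rdfxml")
})

test_that("type-specific parameters parse per the grammar", {
  s <- parse_phylows_uri("/phylows/size/greater/leaf/25")
  expect_equal(s[c("qtype", "direction", "criteria", "size")],
               list(qtype = "size", direction = "greater",
                    criteria = "leaf", size = 25L))
  s <- parse_phylows_uri("/phylows/nca/t1/A/B")
  expect_equal(s$qtype, "nca")
  expect_equal(s$target_id, "t1")
  expect_equal(s$taxa, c("A", "B"))
  s <- parse_phylows_uri("/phylows/msc/t1/Ilex%20anomala/Ilex%20glabra")
  expect_equal(s$taxa, c("Ilex anomala", "Ilex glabra"))
  s <- parse_phylows_uri("/phylows/taxa/A/B?limit=10&offset=5")
  expect_equal(s$limit, 10L)
  expect_equal(s$offset, 5L)
  s <- parse_phylows_uri("/phylows/distance/t1/rf/2")
  expect_equal(s$measure, "rf")
  expect_equal(s$q, 2)
})

test_that("malformed URIs raise distinct structured errors", {
  expect_error(parse_phylows_uri("/other/tree/t1"), "/phylows/")
  expect_error(parse_phylows_uri("/phylows/frobnicate/x"),
               "unknown query type")
  expect_error(parse_phylows_uri("/phylows/nca/t1"), "taxon")
  expect_error(parse_phylows_uri("/phylows/size/greater/leaf/many"),
               "numeral")
  expect_error(parse_phylows_uri("/phylows/size/sideways/leaf/3"),
               "direction")
  expect_error(parse_phylows_uri("/phylows/tree/t1?format=doc"),
               "unknown format")
  expect_error(parse_phylows_uri("/phylows/taxa/A?limit=ten"), "numeral")
})

test_that("every query type round-trips through render and parse", {
  specs <- list(
    parse_phylows_uri("/phylows/tree/TB2:Tr3099?format=rdf"),
    parse_phylows_uri("/phylows/matrix/m1?format=nexus"),
    parse_phylows_uri("/phylows/list?limit=5&offset=2"),
    parse_phylows_uri("/phylows/taxa/Ilex%20anomala/B"),
    parse_phylows_uri("/phylows/msc/t1/A/B?format=newick"),
    parse_phylows_uri("/phylows/nca/t1/A/B/C"),
    parse_phylows_uri("/phylows/author/Piel"),
    parse_phylows_uri("/phylows/method/parsimony"),
    parse_phylows_uri("/phylows/size/equal/internal/7"),
    parse_phylows_uri("/phylows/property/diameter/5"),
    parse_phylows_uri("/phylows/distance/t1/rf/2"),
    parse_phylows_uri("/phylows/stats/treelength"),
    parse_phylows_uri("/phylows/datatype/DNA/A/B"))
  for (s in specs)
    expect_equal(parse_phylows_uri(render_phylows_uri(s)), s,
                 label = s$qtype)
  # taxa containing "/" survive the percent-encoding round trip
  s <- new_query_spec_for_test("taxa", taxa = c("a/b", "plain"))
  expect_equal(parse_phylows_uri(render_phylows_uri(s))$taxa,
               c("a/b", "plain"))
})

test_that("execute dispatches each query type over the store", {
  st <- ws_store()
  r <- phylows(st, "/phylows/nca/t1/A/B")
  expect_equal(r$count, 1)
  t1 <- store_get_tree(st, "t1")
  x <- nearest_common_ancestor(t1, c("A", "B"))
  expect_match(r$payload, x)
  r <- phylows(st, "/phylows/tree/t1?format=newick")
  expect_equal(r$payload, "((A,B),C);")
  r <- phylows(st, "/phylows/tree/t1")   # default tree format is nexml
  expect_equal(xml2::xml_name(xml2::read_xml(r$payload)), "nexml")
  r <- phylows(st, "/phylows/msc/t3/A/B?format=newick")
  expect_equal(r$payload, "(A,B);")
  r <- phylows(st, "/phylows/size/greater/leaf/25")
  expect_equal(r$count, 0)
  expect_equal(r$payload, "")
  r <- phylows(st, "/phylows/taxa/B/C")
  expect_equal(r$count, 3)
  expect_equal(r$payload, "t1\nt2\nt3")
  r <- phylows(st, "/phylows/stats/nodecount")
  parsed <- jsonlite::fromJSON(r$payload)
  expect_equal(parsed$count, 3)
  expect_equal(parsed$mean, mean(c(5, 5, 7)))
  expect_error(phylows(st, "/phylows/tree/zz"), "not found")
})

test_that("pagination is deterministic and reassembles exactly", {
  st <- ws_store()
  full <- strsplit(phylows(st, "/phylows/taxa/B/C")$payload, "\n")[[1]]
  expect_equal(full, sort(full))
  second <- phylows(st, "/phylows/taxa/B/C?limit=1&offset=1")
  expect_equal(second$payload, full[2])
  expect_equal(second$count, 3)   # count reports the total match count
  pages <- character(0)
  for (off in seq(0, length(full), by = 2)) {
    p <- phylows(st, paste0("/phylows/taxa/B/C?limit=2&offset=", off))$payload
    if (nzchar(p)) pages <- c(pages, strsplit(p, "\n")[[1]])
  }
  expect_equal(pages, full)
})

test_that("execution never mutates the store and is repeatable", {
  st <- ws_store()
  before <- st$triples
  p1 <- phylows(st, "/phylows/list")$payload
  p2 <- phylows(st, "/phylows/list")$payload
  expect_identical(p1, p2)
  expect_identical(st$triples, before)
})
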