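# KGML parsing into reaction graphs.

test_that("a linear chain parses into nodes joined by product/substrate edges", {
  fx <- make_kgml("chain", 3)
  g <- parse_kgml(fx$kgml)
  expect_length(g$nodes, 3)
  expect_equal(nrow(g$edges), 2)
  expect_false(g$empty)
  expect_identical(g$map_id, "00010")
  expect_identical(g$organism, "syn")
  # edge labels are the connecting compounds, nodes never compounds
  expect_true(all(grepl("^cpd:", g$edges$compound)))
  expect_true(all(grepl("^rn:", names(g$nodes))))
  # isoenzyme/complex merge: gene and enzyme entries collapse onto one node
  n1 <- g$nodes[["rn:R01"]]
  expect_true("syn:g01" %in% n1$gene_ids)
  expect_identical(n1$ec4, "1.1.1.1")
  expect_identical(n1$ec3, "1.1.1")
})

test_that("edge sets match a brute-force pairwise compound-intersection oracle", {
  for (topo in c("chain", "branch", "cycle", "crossmap")) {
    n <- if (topo == "branch") 5 else 4
    fx <- make_kgml(topo, n)
    g <- parse_kgml(fx$kgml)
    got <- sort(paste(g$edges$from, g$edges$to))
    expect_identical(got, sort(brute_edge_pairs(fx)), label = topo)
  }
})

test_that("reversible reactions are traversable in both directions", {
  fx <- make_kgml("chain", 3, reversible_fraction = 1)
  g <- parse_kgml(fx$kgml, directed = TRUE)
  # from the chain's sink a directed BFS now reaches the source
  tree <- build_bfs_tree(g, "rn:R03")
  expect_true("rn:R01" %in% names(tree$parent))
  # and every forward edge has its mirror
  key <- function(f, t) paste(f, t)
  expect_true(all(key(g$edges$to, g$edges$from) %in%
                    key(g$edges$from, g$edges$to)))
})

test_that("branched maps give the hub the right degree", {
  fx <- make_kgml("branch", 5)
  g <- parse_kgml(fx$kgml)
  # root feeds both branches through one compound
  expect_equal(node_degree(g, "rn:R01"), 2)
  expect_setequal(graph_neighbors(g, "rn:R01"), c("rn:A01", "rn:B01"))
})

test_that("directed and undirected constructions agree on nodes; undirected covers directed", {
  fx <- make_kgml("chain", 4, reversible_fraction = 0.5, seed = 7)
  gd <- parse_kgml(fx$kgml, directed = TRUE)
  gu <- parse_kgml(fx$kgml, directed = FALSE)
  expect_identical(names(gd$nodes), names(gu$nodes))
  undirected_pairs <- unique(apply(gu$edges[, 1:2], 1,
                                   function(r) paste(sort(r), collapse = "|")))
  collapsed_directed <- unique(apply(gd$edges[, 1:2], 1,
                                     function(r) paste(sort(r), collapse = "|")))
  expect_true(all(collapsed_directed %in% undirected_pairs))
})

test_that("maplink relations populate map_links without adding nodes or edges", {
  fx <- make_kgml("crossmap", 4)
  g <- parse_kgml(fx$kgml)
  expect_identical(g$map_links, "rn:R04")
  expect_length(g$nodes, 4)          # the map entry is not a node
  plain <- parse_kgml(make_kgml("chain", 4)$kgml)
  expect_equal(nrow(g$edges), nrow(plain$edges))  # relation adds no edges
})

test_that("malformed XML and reaction-free maps are handled as specified", {
  expect_error(parse_kgml("<pathway><entry></pathway>"), "parse error")
  expect_error(parse_kgml("<notkgml/>"), "pathway")
  empty <- parse_kgml(paste0(
    "<pathway name=\"path:syn00099\" org=\"syn\" number=\"00099\">",
    "<entry id=\"1\" name=\"cpd:C01\" type=\"compound\"/></pathway>"))
  expect_true(empty$empty)
  expect_length(empty$nodes, 0)
})

test_that("the checked-in synthetic glycolysis fragment parses end to end", {
  path <- system.file("extdata", "synthetic-lower-glycolysis.xml",
                      package = "essalign")
  g <- parse_kgml(path)
  expect_length(g$nodes, 3)
  expect_equal(nrow(g$edges), 2 + 2)  # two mirrored at reversible reactions
  expect_setequal(g$nodes[["rn:R01070"]]$gene_ids, c("syn:fbaA", "syn:fbaB"))
  ess <- extract_map_ess(g)
  expect_length(ess, 1)
  expect_identical(ess[[1]]$labels3, c("2.7.1", "4.1.2", "1.2.1"))
  expect_identical(ess[[1]]$labels4, c("2.7.1.11", "4.1.2.13", "1.2.1.12"))
})

test_that("strict metabolic maps are recognised by their numeric code", {
  expect_true(is_strict_map("00010"))
  expect_true(is_strict_map("00230"))
  expect_false(is_strict_map("01100"))
  expect_true(is_strict_map("path:eco00010"))
  expect_true(is_strict_map("00,010"))
  expect_error(is_strict_map("glycolysis"), "invalid map id")
})
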