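# Initialization nodes, BFS trees, and ESS extraction.

test_that("initialization nodes follow the two selection criteria", {
  # linear chain: only the source has no in-map producer
  g <- parse_kgml(make_kgml("chain", 3)$kgml)
  expect_identical(select_initialization_nodes(g), "rn:R01")
  # cycle: every substrate is produced in-map
  gc <- parse_kgml(make_kgml("cycle", 3)$kgml)
  expect_identical(select_initialization_nodes(gc), character(0))
  # cross-map link with degree 1 adds the chain's sink (criterion 2)
  gx <- parse_kgml(make_kgml("crossmap", 4)$kgml)
  expect_identical(select_initialization_nodes(gx), c("rn:R01", "rn:R04"))
})

test_that("BFS trees have the expected shape and leaves exclude the root", {
  g4 <- parse_kgml(make_kgml("chain", 4)$kgml)
  tree <- build_bfs_tree(g4, "rn:R01")
  expect_identical(tree$leaves, "rn:R04")
  depth <- function(v) {
    d <- 0L
    while (v != tree$root) { v <- tree$parent[[v]]; d <- d + 1L }
    d
  }
  expect_equal(depth("rn:R04"), 3)
  # branched: two leaves
  gb <- parse_kgml(make_kgml("branch", 5)$kgml)
  tb <- build_bfs_tree(gb, "rn:R01")
  expect_setequal(tb$leaves, c("rn:A02", "rn:B02"))
  # directed chain rooted at the sink: no forward edges, root-only tree
  ts <- build_bfs_tree(g4, "rn:R04")
  expect_length(ts$leaves, 0)
  expect_length(extract_ess(ts, g4), 0)
  expect_error(build_bfs_tree(g4, "rn:R99"), "unknown node")
})

test_that("each tree yields exactly one ESS per leaf, read root-to-leaf", {
  gb <- parse_kgml(make_kgml("branch", 7)$kgml)
  tb <- build_bfs_tree(gb, "rn:R01")
  ess <- extract_ess(tb, gb)
  expect_length(ess, length(tb$leaves))
  fx <- make_kgml("chain", 4)
  g <- parse_kgml(fx$kgml)
  e <- extract_ess(build_bfs_tree(g, "rn:R01"), g)
  expect_length(e, 1)
  expect_identical(e[[1]]$labels3, fx$labels)
  # four-level labels are refinements of the three-level ones
  expect_identical(ec3_prefix(e[[1]]$labels4), e[[1]]$labels3)
  expect_identical(e[[1]]$organism, "syn")
  expect_identical(e[[1]]$map_id, "00010")
})

test_that("ESS per map = sum of leaves over initialization trees, and every ESS is a graph walk", {
  for (topo in c("chain", "branch", "cycle", "crossmap")) {
    for (directed in c(TRUE, FALSE)) {
      n <- if (topo == "branch") 5 else 4
      g <- parse_kgml(make_kgml(topo, n)$kgml, directed = directed)
      roots <- select_initialization_nodes(g)
      leaves_total <- sum(vapply(roots, function(r) {
        length(build_bfs_tree(g, r)$leaves)
      }, integer(1)))
      ess <- extract_map_ess(g)
      expect_length(ess, leaves_total)
      edge_key <- paste(g$edges$from, g$edges$to)
      if (!g$directed) edge_key <- c(edge_key, paste(g$edges$to, g$edges$from))
      for (e in ess) {
        steps <- e$node_ids
        for (k in seq_len(length(steps) - 1)) {
          expect_true(paste(steps[k], steps[k + 1]) %in% edge_key,
                      label = sprintf("%s step %d", topo, k))
        }
      }
    }
  }
})

test_that("directed extraction never emits more ESS than undirected", {
  for (topo in c("chain", "branch", "cycle", "crossmap")) {
    n <- if (topo == "branch") 5 else 4
    fx <- make_kgml(topo, n)
    nd <- length(extract_map_ess(parse_kgml(fx$kgml, directed = TRUE)))
    nu <- length(extract_map_ess(parse_kgml(fx$kgml, directed = FALSE)))
    expect_lte(nd, nu)
  }
})

test_that("non-redundant filtering keeps one representative with full provenance", {
  mk <- function(labs, org, map) {
    new_ess(labs, paste0(labs, ".1"), org, map,
            genes = as.list(paste0(org, ":g", seq_along(labs))),
            node_ids = paste0("rn:R", seq_along(labs)))
  }
  a <- mk(c("1.1.1", "2.7.1"), "eco", "00010")
  b <- mk(c("1.1.1", "2.7.1"), "bsu", "00020")
  c2 <- mk(c("2.7.1", "1.1.1"), "eco", "00010")   # reversal is distinct
  nr <- make_nonredundant(list(a, b, c2))
  expect_length(nr$nress, 2)
  expect_length(nr$redundancy[["1.1.1:2.7.1"]], 2)
  orgs <- vapply(nr$redundancy[["1.1.1:2.7.1"]], `[[`, character(1), "organism")
  expect_setequal(orgs, c("eco", "bsu"))
  # k distinct in, k out; deduplication is idempotent
  distinct <- list(a, c2)
  nr2 <- make_nonredundant(distinct)
  expect_length(nr2$nress, 2)
  nr3 <- make_nonredundant(nr2$nress)
  expect_identical(vapply(nr3$nress, function(e) format_ess(e$labels3), ""),
                   vapply(nr2$nress, function(e) format_ess(e$labels3), ""))
})
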