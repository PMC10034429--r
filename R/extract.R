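#' Select BFS initialization nodes of a pathway graph
#'
#' Initialization nodes are the roots from which BFS trees (and hence ESS)
#' are grown.  Two criteria apply, and their union is returned:
#' (1) reactions none of whose substrates is produced by any other reaction
#' in the map (pathway entry points); (2) reactions adjacent to a cross-map
#' link entry and with fewer than 3 distinct neighbors — peripheral nodes
#' that connect to other metabolic maps.  Criterion 1 uses the nominal
#' substrate/product sets (reversibility affects only edges).
#'
#' @param graph a `pathway_graph`.
#' @return character vector of node ids, sorted for determinism (possibly
#'   empty, e.g. for a pure cycle).
#' @export
select_initialization_nodes <- function(graph) {
  stopifnot(inherits(graph, "pathway_graph"))
  ids <- names(graph$nodes)
  crit1 <- character(0L)
  for (v in ids) {
    produced <- unique(unlist(lapply(graph$nodes[setdiff(ids, v)],
                                     `[[`, "products")))
    if (!any(graph$nodes[[v]]$substrates %in% produced)) {
      crit1 <- c(crit1, v)
    }
  }
  crit2 <- graph$map_links[vapply(graph$map_links, function(v) {
    node_degree(graph, v) < 3L
  }, logical(1L))]
  sort(union(crit1, crit2))
}

#' Build a BFS tree rooted at an initialization node
#'
#' Standard breadth-first search; in directed mode only forward edges are
#' traversed (which is why the directed option tends to yield fewer ESS).
#' Neighbor visiting order is by sorted node id so the tree — and every ESS
#' derived from it — is reproducible.
#'
#' @param graph a `pathway_graph`.
#' @param root node id present in the graph.
#' @return an object of class `bfs_tree`: list with `root`, `parent` (named
#'   character map child -> parent), `children` (named list), and `leaves`
#'   (non-root nodes with no children, sorted).
#' @export
build_bfs_tree <- function(graph, root) {
  stopifnot(inherits(graph, "pathway_graph"))
  if (!root %in% names(graph$nodes)) {
    stop(sprintf("unknown node '%s'", root), call. = FALSE)
  }
  parent <- character(0L)
  children <- stats::setNames(vector("list", 0L), character(0L))
  visited <- root
  queue <- root
  while (length(queue) > 0L) {
    v <- queue[[1L]]
    queue <- queue[-1L]
    nb <- setdiff(graph_neighbors(graph, v), visited)
    for (w in nb) {
      parent[[w]] <- v
      children[[v]] <- c(children[[v]], w)
      visited <- c(visited, w)
      queue <- c(queue, w)
    }
  }
  leaves <- sort(setdiff(visited, c(root, names(children))))
  structure(list(root = root, parent = parent, children = children,
                 leaves = leaves),
            class = "bfs_tree")
}

# Representative (labels4, labels3) step label for a reaction node: the
# lexicographically smallest three-level EC and the smallest four-level EC
# beneath it; gene->EC associations stay intact in the database.
node_step_label <- function(node) {
  if (identical(node$ec3, EC_UNASSIGNED) ||
      (length(node$ec3) == 1L && node$ec3 == EC_UNASSIGNED)) {
    return(c(ec3 = EC_UNASSIGNED, ec4 = EC_UNASSIGNED))
  }
  ec3 <- sort(node$ec3)[[1L]]
  cand <- node$ec4[ec3_prefix(node$ec4) == ec3]
  c(ec3 = ec3, ec4 = sort(cand)[[1L]])
}

new_ess <- function(labels3, labels4, organism, map_id, genes, node_ids) {
  structure(list(labels3 = labels3, labels4 = labels4, organism = organism,
                 map_id = map_id, genes = genes, node_ids = node_ids),
            class = "ess")
}

#' @export
print.ess <- function(x, ...) {
  cat(sprintf("<ess> %s  (%s, map %s)\n", format_ess(x$labels3),
              x$organism, x$map_id))
  invisible(x)
}

#' Extract enzymatic step sequences from a BFS tree
#'
#' One ESS per leaf: the path from the leaf is traced back to the root and
#' reported in root-to-leaf order (the metabolic flow direction), with the
#' gene identifiers of each step translated to EC numbers at four and three
#' classification levels.  A tree therefore produces as many sequences as
#' it has leaves; paths shorter than `min_length` steps are discarded.
#'
#' @param tree a `bfs_tree` built from `graph`.
#' @param graph the source `pathway_graph`.
#' @param min_length minimum number of steps for an ESS (default 2; a
#'   one-step sequence carries no step-order information).
#' @return list of `ess` objects, ordered by leaf id.
#' @export
extract_ess <- function(tree, graph, min_length = 2L) {
  stopifnot(inherits(tree, "bfs_tree"), inherits(graph, "pathway_graph"))
  out <- list()
  for (leaf in tree$leaves) {
    path <- leaf
    v <- leaf
    while (v != tree$root) {
      v <- tree$parent[[v]]
      path <- c(v, path)
    }
    if (length(path) < min_length) next
    labs <- vapply(path, function(id) node_step_label(graph$nodes[[id]]),
                   character(2L))
    out[[length(out) + 1L]] <- new_ess(
      labels3 = unname(labs["ec3", ]),
      labels4 = unname(labs["ec4", ]),
      organism = graph$organism,
      map_id = graph$map_id,
      genes = lapply(path, function(id) graph$nodes[[id]]$gene_ids),
      node_ids = path
    )
  }
  out
}

#' Extract all ESS of a metabolic map
#'
#' Convenience pipeline: initialization nodes -> one BFS tree per node ->
#' ESS from every tree, concatenated in initialization-node order.
#'
#' @inheritParams extract_ess
#' @return list of `ess` objects.
#' @export
extract_map_ess <- function(graph, min_length = 2L) {
  roots <- select_initialization_nodes(graph)
  out <- list()
  for (r in roots) {
    tree <- build_bfs_tree(graph, r)
    out <- c(out, extract_ess(tree, graph, min_length = min_length))
  }
  out
}

#' Collapse identical ESS into a non-redundant set
#'
#' The same ESS frequently recurs across organisms and maps; the
#' non-redundant dataset (nrESS) keeps one representative per distinct
#' three-level label sequence while a redundancy map links each
#' representative back to every original occurrence (organism, map, gene
#' ids per step).
#'
#' @param ess_list list of `ess` objects.
#' @return list with `nress` (list of representative `ess`, first
#'   occurrence kept) and `redundancy` (named list keyed by the
#'   colon-joined label sequence; each element is a list of provenance
#'   records `organism`/`map_id`/`genes`).
#' @export
make_nonredundant <- function(ess_list) {
  keys <- vapply(ess_list, function(e) format_ess(e$labels3), character(1L))
  keep <- !duplicated(keys)
  nress <- ess_list[keep]
  redundancy <- stats::setNames(vector("list", sum(keep)), keys[keep])
  for (i in seq_along(ess_list)) {
    k <- keys[[i]]
    e <- ess_list[[i]]
    redundancy[[k]] <- c(redundancy[[k]], list(list(
      organism = e$organism, map_id = e$map_id, genes = e$genes
    )))
  }
  list(nress = nress, redundancy = redundancy)
}
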