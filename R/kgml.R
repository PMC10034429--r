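#' Parse a KGML metabolic map into a reaction graph
#'
#' Reads a KGML (KEGG pathway XML) document and builds a graph in which the
#' nodes are enzymatic reactions and the edges are product/substrate
#' relations: reactions A and B are joined by an edge labelled with compound
#' C iff C is a product of A and a substrate of B.  Reversibility is read
#' from the reaction `type` attribute; a reversible reaction contributes
#' traversable connectivity in both directions (each edge incident to a
#' reversible reaction is mirrored).
#'
#' Entries of type `gene`/`ortholog` attached to a reaction supply gene
#' identifiers; `ec:`-prefixed name tokens (as carried by enzyme entries in
#' reference maps) supply four-level EC numbers.  Multiple entries
#' catalysing the same reaction (isoenzymes, complexes) are merged into one
#' node holding the union of their identifiers.  A reaction with no EC
#' token is labelled with the sentinel "9.9.9".  Compounds are never nodes;
#' they exist only as edge labels.  `map`-type entries are never nodes
#' either: reactions connected to one through a `maplink` relation are
#' recorded in `map_links` (used by initialization-node criterion 2).
#' `relation` elements contribute no edges.
#'
#' @param source path to a KGML file, a KGML string, or an `xml2` document.
#' @param directed logical; if `FALSE`, consumers of the graph ignore edge
#'   direction.
#' @return an object of class `pathway_graph`: a list with `map_id`,
#'   `organism`, `nodes` (named list of reaction nodes with `gene_ids`,
#'   `ec4`, `ec3`, `substrates`, `products`, `reversible`), `edges` (a
#'   data.frame `from`/`to`/`compound`, one row per directed edge),
#'   `directed`, `map_links`, and `empty` (flag set when the map has no
#'   reactions).
#' @export
parse_kgml <- function(source, directed = TRUE) {
  doc <- tryCatch(
    xml2::read_xml(source),
    error = function(e) {
      stop("KGML parse error: ", conditionMessage(e), call. = FALSE)
    }
  )
  root <- xml2::xml_name(doc)
  if (!identical(root, "pathway")) {
    stop(sprintf("KGML parse error: expected <pathway> root, found <%s>", root),
         call. = FALSE)
  }
  map_id <- xml2::xml_attr(doc, "number")
  if (is.na(map_id)) {
    nm <- xml2::xml_attr(doc, "name")
    map_id <- if (!is.na(nm)) gsub("[^0-9]", "", nm) else NA_character_
  }
  organism <- xml2::xml_attr(doc, "org")

  entries <- xml2::xml_find_all(doc, "./entry")
  entry_tbl <- lapply(entries, function(e) {
    list(
      id       = xml2::xml_attr(e, "id"),
      name     = strsplit(xml2::xml_attr(e, "name"), "\\s+")[[1L]],
      type     = xml2::xml_attr(e, "type"),
      reaction = {
        r <- xml2::xml_attr(e, "reaction")
        if (is.na(r)) character(0L) else strsplit(r, "\\s+")[[1L]]
      }
    )
  })
  names(entry_tbl) <- vapply(entry_tbl, `[[`, character(1L), "id")

  reactions <- xml2::xml_find_all(doc, "./reaction")
  nodes <- list()
  for (r in reactions) {
    rid <- xml2::xml_attr(r, "name")
    if (is.na(rid)) rid <- xml2::xml_attr(r, "id")
    rtype <- xml2::xml_attr(r, "type")
    subs <- xml2::xml_attr(xml2::xml_find_all(r, "./substrate"), "name")
    prods <- xml2::xml_attr(xml2::xml_find_all(r, "./product"), "name")
    if (rid %in% names(nodes)) {
      # same reaction listed twice: merge compound sets
      nodes[[rid]]$substrates <- union(nodes[[rid]]$substrates, subs)
      nodes[[rid]]$products <- union(nodes[[rid]]$products, prods)
      nodes[[rid]]$reversible <- nodes[[rid]]$reversible ||
        identical(rtype, "reversible")
      next
    }
    nodes[[rid]] <- list(
      reaction_id = rid,
      gene_ids = character(0L),
      ec4 = character(0L),
      ec3 = character(0L),
      substrates = unique(subs),
      products = unique(prods),
      reversible = identical(rtype, "reversible")
    )
  }

  # attach entries (genes, enzymes) to the reactions they catalyse
  rtokens <- lapply(names(nodes), function(rid) strsplit(rid, "\\s+")[[1L]])
  names(rtokens) <- names(nodes)
  for (e in entry_tbl) {
    if (length(e$reaction) == 0L) next
    for (rid in names(nodes)) {
      if (!any(e$reaction %in% rtokens[[rid]])) next
      ec <- sub("^ec:", "", grep("^ec:", e$name, value = TRUE))
      other <- grep("^ec:", e$name, value = TRUE, invert = TRUE)
      nodes[[rid]]$ec4 <- union(nodes[[rid]]$ec4, ec)
      if (e$type %in% c("gene", "ortholog")) {
        nodes[[rid]]$gene_ids <- union(nodes[[rid]]$gene_ids, other)
      }
    }
  }
  for (rid in names(nodes)) {
    if (length(nodes[[rid]]$ec4) == 0L) {
      nodes[[rid]]$ec4 <- EC_UNASSIGNED
      nodes[[rid]]$ec3 <- EC_UNASSIGNED
    } else {
      nodes[[rid]]$ec3 <- unique(ec3_prefix(nodes[[rid]]$ec4))
    }
    if (length(nodes[[rid]]$gene_ids) == 0L) {
      # reference maps carry no gene entries; fall back to the EC tokens
      ecs <- nodes[[rid]]$ec4
      nodes[[rid]]$gene_ids <- if (any(ecs != EC_UNASSIGNED)) {
        paste0("ec:", ecs[ecs != EC_UNASSIGNED])
      } else rid
    }
  }

  # product -> substrate edges, then mirror edges at reversible reactions
  ids <- names(nodes)
  from <- to <- compound <- character(0L)
  for (a in ids) {
    for (b in ids) {
      if (a == b) next
      shared <- intersect(nodes[[a]]$products, nodes[[b]]$substrates)
      if (length(shared) > 0L) {
        from <- c(from, rep(a, length(shared)))
        to <- c(to, rep(b, length(shared)))
        compound <- c(compound, shared)
      }
    }
  }
  edges <- data.frame(from = from, to = to, compound = compound,
                      stringsAsFactors = FALSE)
  if (nrow(edges) > 0L) {
    rev_mask <- vapply(seq_len(nrow(edges)), function(k) {
      nodes[[edges$from[k]]]$reversible || nodes[[edges$to[k]]]$reversible
    }, logical(1L))
    if (any(rev_mask)) {
      mirrored <- data.frame(from = edges$to[rev_mask], to = edges$from[rev_mask],
                             compound = edges$compound[rev_mask],
                             stringsAsFactors = FALSE)
      edges <- unique(rbind(edges, mirrored))
      rownames(edges) <- NULL
    }
  }

  # maplink relations mark reactions adjacent to cross-map entries
  map_links <- character(0L)
  map_entry_ids <- names(entry_tbl)[vapply(entry_tbl, function(e) {
    identical(e$type, "map")
  }, logical(1L))]
  for (rel in xml2::xml_find_all(doc, "./relation")) {
    if (!identical(xml2::xml_attr(rel, "type"), "maplink")) next
    ends <- c(xml2::xml_attr(rel, "entry1"), xml2::xml_attr(rel, "entry2"))
    if (!any(ends %in% map_entry_ids)) next
    partner <- setdiff(ends, map_entry_ids)
    for (pid in partner) {
      e <- entry_tbl[[pid]]
      if (is.null(e)) next
      for (rid in names(nodes)) {
        if (any(e$reaction %in% rtokens[[rid]])) {
          map_links <- union(map_links, rid)
        }
      }
    }
  }

  structure(
    list(map_id = map_id, organism = organism, nodes = nodes, edges = edges,
         directed = isTRUE(directed), map_links = map_links,
         empty = length(nodes) == 0L),
    class = "pathway_graph"
  )
}

#' @export
print.pathway_graph <- function(x, ...) {
  cat(sprintf("<pathway_graph> map %s (%s), %d reactions, %d directed edges, %s\n",
              x$map_id, x$organism, length(x$nodes), nrow(x$edges),
              if (x$directed) "directed" else "undirected"))
  invisible(x)
}

#' Is a map code a strict metabolic map?
#'
#' The method works only with strict metabolic maps — those describing
#' consecutive enzymatic steps with product/substrate relations — which are
#' recognised by a KEGG map code numerically below 01000 (e.g. 00010,
#' Glycolysis/Gluconeogenesis; 00230, Purine metabolism).  Global overview
#' maps (codes >= 01000) are excluded.
#'
#' @param map_id map code string containing a 5-digit numeric code, possibly
#'   with an organism prefix ("eco00010") or punctuation ("00,010").
#' @return logical.
#' @export
is_strict_map <- function(map_id) {
  if (!is.character(map_id) || length(map_id) != 1L || is.na(map_id)) {
    stop("invalid map id", call. = FALSE)
  }
  digits <- gsub("[^0-9]", "", map_id)
  if (nchar(digits) < 5L) {
    stop(sprintf("invalid map id '%s': no 5-digit numeric code", map_id),
         call. = FALSE)
  }
  code <- as.integer(substr(digits, nchar(digits) - 4L, nchar(digits)))
  code < 1000L
}

# Neighbors of `v` respecting the graph mode: forward edges only when
# directed, union of both directions otherwise.  Sorted for determinism.
graph_neighbors <- function(graph, v) {
  e <- graph$edges
  out <- e$to[e$from == v]
  if (!graph$directed) out <- c(out, e$from[e$to == v])
  sort(unique(out))
}

# Undirected degree: number of distinct neighbors irrespective of direction.
node_degree <- function(graph, v) {
  e <- graph$edges
  length(unique(c(e$to[e$from == v], e$from[e$to == v])))
}
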