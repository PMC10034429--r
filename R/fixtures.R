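#' Generate a synthetic KGML map with known expected ESS
#'
#' Emits a minimal valid KGML document (entries, reactions, substrates,
#' products, and — for the cross-map topology — a map entry with a maplink
#' relation) together with the ground-truth ESS that extraction must
#' produce from it.  Topologies:
#' \describe{
#'   \item{chain}{R1 -> C1 -> R2 -> ... -> Rn; one initialization node, one
#'     leaf, one ESS covering the whole chain.}
#'   \item{branch}{one root feeding two branches of equal length
#'     (`n_reactions` odd); two leaves, two ESS.}
#'   \item{cycle}{closed loop; every substrate is produced in-map, so no
#'     initialization nodes and no ESS.}
#'   \item{crossmap}{a chain whose last reaction also links to another
#'     metabolic map (degree 1 < 3, initialization criterion 2); directed
#'     extraction yields the forward ESS only, undirected additionally the
#'     reversed one.}
#' }
#' EC labels are assigned from `ec_alphabet`, recycled along the reactions
#' in construction order (root first, then branch A, then branch B for the
#' branch topology).  `reversible_fraction` marks reactions reversible at
#' random under `seed`; it is honoured for chain/branch (where the expected
#' ESS are unaffected) and forced to 0 for cycle/crossmap, whose
#' closed-form expectations depend on edge direction.
#'
#' @param topology one of `"chain"`, `"branch"`, `"cycle"`, `"crossmap"`.
#' @param n_reactions number of reactions (odd and >= 3 for `branch`).
#' @param ec_alphabet three-level EC labels to recycle over the reactions.
#' @param reversible_fraction fraction of reactions marked reversible.
#' @param seed RNG seed for the reversibility draw.
#' @param organism,map_id KGML header fields.
#' @return list with `kgml` (XML text), `expected` (list `directed` /
#'   `undirected` of colon-joined expected ESS, in extraction order),
#'   `node_ids`, `labels` (per-reaction three-level ECs) and `reversible`.
#' @export
make_kgml <- function(topology = c("chain", "branch", "cycle", "crossmap"),
                      n_reactions = 4L,
                      ec_alphabet = c("1.1.1", "2.7.1", "3.1.3", "4.1.2",
                                      "5.3.1", "6.2.1"),
                      reversible_fraction = 0, seed = 1L,
                      organism = "syn", map_id = "00010") {
  topology <- match.arg(topology)
  n <- as.integer(n_reactions)
  if (n < 1L) stop("n_reactions must be >= 1", call. = FALSE)
  if (n > 99L) stop("n_reactions must be <= 99", call. = FALSE)
  if (topology == "branch" && (n < 3L || n %% 2L == 0L)) {
    stop("branch topology needs an odd n_reactions >= 3", call. = FALSE)
  }

  cpd <- function(k) sprintf("cpd:C%02d", k)
  labels <- ec_alphabet[((seq_len(n) - 1L) %% length(ec_alphabet)) + 1L]

  # per-reaction id / substrate / product compound sets
  if (topology == "chain" || topology == "crossmap") {
    ids <- sprintf("rn:R%02d", seq_len(n))
    subs <- lapply(seq_len(n), function(i) cpd(i - 1L))
    prods <- lapply(seq_len(n), function(i) cpd(i))
  } else if (topology == "cycle") {
    ids <- sprintf("rn:R%02d", seq_len(n))
    subs <- lapply(seq_len(n), function(i) cpd(i - 1L))
    prods <- lapply(seq_len(n), function(i) cpd(i %% n))
  } else { # branch
    L <- (n - 1L) %/% 2L
    ids <- c("rn:R01", sprintf("rn:A%02d", seq_len(L)),
             sprintf("rn:B%02d", seq_len(L)))
    bc <- function(branch, k) sprintf("cpd:%s%02d", branch, k)
    subs <- c(list(cpd(0L)),
              lapply(seq_len(L), function(k) if (k == 1L) cpd(1L) else bc("A", k - 1L)),
              lapply(seq_len(L), function(k) if (k == 1L) cpd(1L) else bc("B", k - 1L)))
    prods <- c(list(cpd(1L)),
               lapply(seq_len(L), function(k) bc("A", k)),
               lapply(seq_len(L), function(k) bc("B", k)))
  }

  reversible <- if (topology %in% c("cycle", "crossmap")) {
    rep(FALSE, n)
  } else {
    with_seed(seed, stats::runif(n) < reversible_fraction)
  }

  # expected ESS (colon-joined three-level labels), in extraction order
  fwd <- format_ess(labels)
  expected <- switch(topology,
    chain = if (n >= 2L) {
      list(directed = fwd, undirected = fwd)
    } else {
      list(directed = character(0L), undirected = character(0L))
    },
    cycle = list(directed = character(0L), undirected = character(0L)),
    crossmap = if (n >= 2L) {
      list(directed = fwd,
           undirected = c(fwd, format_ess(rev(labels))))
    } else {
      list(directed = character(0L), undirected = character(0L))
    },
    branch = {
      L <- (n - 1L) %/% 2L
      essA <- format_ess(labels[c(1L, 1L + seq_len(L))])
      essB <- format_ess(labels[c(1L, 1L + L + seq_len(L))])
      list(directed = c(essA, essB), undirected = c(essA, essB))
    }
  )
  expected <- lapply(expected, unlist)

  # assemble the KGML document
  xml <- c(
    "<?xml version=\"1.0\"?>",
    sprintf("<pathway name=\"path:%s%s\" org=\"%s\" number=\"%s\" title=\"synthetic map\">",
            organism, map_id, organism, map_id)
  )
  for (i in seq_len(n)) {
    xml <- c(xml,
      sprintf("  <entry id=\"%d\" name=\"%s:g%02d\" type=\"gene\" reaction=\"%s\"/>",
              i, organism, i, ids[i]),
      sprintf("  <entry id=\"%d\" name=\"ec:%s.1\" type=\"enzyme\" reaction=\"%s\"/>",
              100L + i, labels[i], ids[i]))
  }
  all_cpds <- unique(unlist(c(subs, prods)))
  for (k in seq_along(all_cpds)) {
    xml <- c(xml, sprintf("  <entry id=\"%d\" name=\"%s\" type=\"compound\"/>",
                          300L + k, all_cpds[k]))
  }
  if (topology == "crossmap") {
    xml <- c(xml,
      sprintf("  <entry id=\"900\" name=\"path:%s00020\" type=\"map\"/>", organism),
      sprintf("  <relation entry1=\"%d\" entry2=\"900\" type=\"maplink\">", n),
      sprintf("    <subtype name=\"compound\" value=\"%d\"/>",
              300L + match(prods[[n]][1L], all_cpds)),
      "  </relation>")
  }
  cpd_id <- function(name) 300L + match(name, all_cpds)
  for (i in seq_len(n)) {
    xml <- c(xml,
      sprintf("  <reaction id=\"%d\" name=\"%s\" type=\"%s\">",
              200L + i, ids[i],
              if (reversible[i]) "reversible" else "irreversible"),
      vapply(subs[[i]], function(s) {
        sprintf("    <substrate id=\"%d\" name=\"%s\"/>", cpd_id(s), s)
      }, character(1L)),
      vapply(prods[[i]], function(p) {
        sprintf("    <product id=\"%d\" name=\"%s\"/>", cpd_id(p), p)
      }, character(1L)),
      "  </reaction>")
  }
  xml <- c(xml, "</pathway>")

  list(kgml = paste(xml, collapse = "\n"), expected = expected,
       node_ids = ids, labels = labels, reversible = reversible,
       substrates = stats::setNames(subs, ids),
       products = stats::setNames(prods, ids))
}

#' Generate a synthetic ESS database with known family structure
#'
#' Families of near-identical step sequences for exercising batch
#' alignment and the significance machinery: each family derives from one
#' ancestor sequence by point EC substitutions at `mutation_rate` per
#' position.  Families occupy disjoint EC top-level classes (at most 7
#' families), so cross-family steps are maximally dissimilar (score 1)
#' while within-family steps differ at deeper levels only.
#'
#' @param n_families number of families (1..7).
#' @param family_size sequences per family (duplicates are kept — with
#'   `mutation_rate = 0` a family is `family_size` identical copies).
#' @param mutation_rate per-position substitution probability in \[0, 1\].
#' @param seed RNG seed; a fixed seed reproduces the database exactly.
#' @param length_range inclusive range of sequence lengths (sampled per
#'   family).
#' @return list with `seqs` (character vector of colon-joined ESS) and
#'   `family` (integer family index per sequence).
#' @export
make_ess_db <- function(n_families = 2L, family_size = 5L,
                        mutation_rate = 0.1, seed = 1L,
                        length_range = c(5L, 10L)) {
  if (n_families < 1L || n_families > 7L) {
    stop("n_families must be between 1 and 7 (disjoint EC classes)",
         call. = FALSE)
  }
  if (family_size < 1L) stop("family_size must be >= 1", call. = FALSE)
  if (mutation_rate < 0 || mutation_rate > 1) {
    stop("mutation_rate must lie in [0, 1]", call. = FALSE)
  }
  with_seed(seed, {
    seqs <- character(0L)
    family <- integer(0L)
    for (f in seq_len(n_families)) {
      L <- sample(seq.int(length_range[1L], length_range[2L]), 1L)
      anc <- sprintf("%d.%d.%d", f, sample(9L, L, replace = TRUE),
                     sample(9L, L, replace = TRUE))
      for (k in seq_len(family_size)) {
        member <- anc
        hits <- which(stats::runif(L) < mutation_rate)
        for (p in hits) {
          repeat {
            cand <- sprintf("%d.%d.%d", f, sample(9L, 1L), sample(9L, 1L))
            if (cand != member[p]) break
          }
          member[p] <- cand
        }
        seqs <- c(seqs, format_ess(member))
        family <- c(family, f)
      }
    }
    list(seqs = seqs, family = family)
  })
}
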