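# Independent oracles used across the suite.

# Brute-force minimum alignment cost by naive enumeration of all monotone
# alignments (plain recursion, no DP table) -- deliberately independent of
# the iterative matrix code in nw_align().
brute_align_cost <- function(s1, s2, lookup, gap = 1) {
  rec <- function(i, j) {
    if (i == 0L) return(j * gap)
    if (j == 0L) return(i * gap)
    min(rec(i - 1L, j - 1L) + lookup(s1[i], s2[j]),
        rec(i - 1L, j) + gap,
        rec(i, j - 1L) + gap)
  }
  rec(length(s1), length(s2))
}

# All sequences of length 1..maxlen over an alphabet, as a list of vectors.
all_label_seqs <- function(alphabet, maxlen) {
  out <- list()
  for (L in seq_len(maxlen)) {
    grid <- do.call(expand.grid,
                    c(rep(list(alphabet), L), stringsAsFactors = FALSE))
    out <- c(out, lapply(seq_len(nrow(grid)),
                         function(r) unname(unlist(grid[r, ]))))
  }
  out
}

# Brute-force count of directed product/substrate edges in a make_kgml()
# fixture, by pairwise compound intersection of the nominal sets.
brute_edge_pairs <- function(fx) {
  ids <- fx$node_ids
  out <- character(0L)
  for (a in ids) {
    for (b in ids) {
      if (a == b) next
      if (length(intersect(fx$products[[a]], fx$substrates[[b]])) > 0L) {
        out <- c(out, paste(a, b))
      }
    }
  }
  out
}

random_ess_labels <- function(len, alphabet) {
  sample(alphabet, len, replace = TRUE)
}

# A small varied EC alphabet producing all dissimilarity tiers
# (0, 1/26, 11/26, 1) under the default weights.
tiered_alphabet <- function() c("1.2.3", "1.2.9", "1.3.3", "2.7.1")
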