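#' Shannon entropy of one EC-classification column
#'
#' The dissimilarity of aligned enzymatic steps is built from the Shannon
#' entropy of each EC classification level treated as an alignment column:
#' \eqn{H = -\sum_i p_i \log_2 p_i}, where \eqn{p_i} is the frequency of
#' symbol \eqn{i} in the column.  For the pairwise case (two symbols) this
#' reduces to 0 when the symbols are equal and 1 when they differ.
#'
#' @param symbols character (or atomic) vector of level values, one per
#'   sequence in the column.
#' @return entropy in bits (non-negative).
#' @examples
#' column_entropy(c("2", "2"))        # 0
#' column_entropy(c("2", "3"))        # 1
#' column_entropy(c("1", "1", "2", "2"))  # 1
#' @export
column_entropy <- function(symbols) {
  if (length(symbols) == 0L) {
    stop("entropy of an empty column is undefined", call. = FALSE)
  }
  p <- as.numeric(table(symbols)) / length(symbols)
  -sum(p * log2(p))
}

check_weights <- function(weights) {
  if (!is.numeric(weights) || length(weights) != 3L || any(weights < 0) ||
      sum(weights) <= 0) {
    stop("weights must be three non-negative numbers with positive sum",
         call. = FALSE)
  }
  weights
}

check_scoring_labels <- function(labels) {
  if (any(labels == EC_GAP)) {
    stop("gap labels are handled by the aligner, not by EC scoring",
         call. = FALSE)
  }
  bad <- which(!is_ec_label(labels))
  if (length(bad) > 0L) {
    stop(sprintf("malformed EC label '%s'", labels[bad[1L]]), call. = FALSE)
  }
  invisible(labels)
}

#' Entropy-based dissimilarity of a column of EC numbers (ECS)
#'
#' The general multi-sequence form: the weighted mean of the per-level
#' Shannon entropies of the three EC classification levels,
#' \deqn{ECS = (w_1 H_1 + w_2 H_2 + w_3 H_3) / (w_1 + w_2 + w_3).}
#' For a pair of EC numbers each \eqn{H_l \in \{0, 1\}} so the value lies in
#' \[0, 1\].  Note that the pairwise substitution matrix
#' ([ec_dissimilarity()]) additionally applies the hierarchy override and
#' can therefore differ from this raw value.
#'
#' @param ecs character vector of three-level EC labels (no gaps).
#' @param weights numeric(3) level weights; default `c(15, 10, 1)`.
#' @return dissimilarity value.
#' @examples
#' ecs_dissimilarity(c("1.2.7", "1.2.7"))  # 0
#' ecs_dissimilarity(c("4.3.1", "4.3.2"))  # 1/26
#' ecs_dissimilarity(c("2.3.1", "2.4.1"))  # 10/26 (no hierarchy override)
#' @export
ecs_dissimilarity <- function(ecs, weights = DEFAULT_EC_WEIGHTS) {
  check_weights(weights)
  if (length(ecs) == 0L) stop("empty EC column", call. = FALSE)
  check_scoring_labels(ecs)
  parts <- strsplit(ecs, ".", fixed = TRUE)
  H <- vapply(1:3, function(l) {
    column_entropy(vapply(parts, `[[`, character(1L), l))
  }, numeric(1L))
  sum(weights * H) / sum(weights)
}

#' Hierarchy-overridden pairwise EC dissimilarity (substitution-matrix entry)
#'
#' The substitution matrix S respects the EC hierarchy: a mismatch at the
#' first classification level scores the maximum dissimilarity 1 regardless
#' of the deeper levels; a mismatch at the second level forces the third
#' level to count as mismatched too.  With weights \eqn{(w_1, w_2, w_3)}:
#' identical labels score 0; a level-3-only mismatch scores
#' \eqn{w_3/\sum w}; a level-2 mismatch scores \eqn{(w_2+w_3)/\sum w}; a
#' level-1 mismatch scores 1.  The sentinel "9.9.9" scores 1 against every
#' other label and 0 against itself.
#'
#' @param ec1,ec2 three-level EC labels (no gaps).
#' @inheritParams ecs_dissimilarity
#' @return dissimilarity in \[0, 1\].
#' @examples
#' ec_dissimilarity("1.2.7", "3.2.2")  # 1
#' ec_dissimilarity("2.3.1", "2.4.1")  # 11/26 = 0.4230769
#' ec_dissimilarity("4.3.1", "4.3.2")  # 1/26  = 0.0384615
#' @export
ec_dissimilarity <- function(ec1, ec2, weights = DEFAULT_EC_WEIGHTS) {
  check_weights(weights)
  check_scoring_labels(c(ec1, ec2))
  if (ec1 == ec2) return(0)
  if (ec1 == EC_UNASSIGNED || ec2 == EC_UNASSIGNED) return(1)
  p1 <- strsplit(ec1, ".", fixed = TRUE)[[1L]]
  p2 <- strsplit(ec2, ".", fixed = TRUE)[[1L]]
  tot <- sum(weights)
  if (p1[1L] != p2[1L]) return(1)
  if (p1[2L] != p2[2L]) return((weights[2L] + weights[3L]) / tot)
  if (p1[3L] != p2[3L]) return(weights[3L] / tot)
  0
}

#' Build the full EC substitution matrix
#'
#' Precomputes [ec_dissimilarity()] for every pair of labels.  The
#' unassigned sentinel "9.9.9" is always included as a row/column.  The
#' label universe is whatever EC set the caller supplies (typically all
#' three-level ECs occurring in an ESS database); the matrix is symmetric
#' with a zero diagonal and values in \[0, 1\].
#'
#' @param labels character vector of distinct three-level EC labels.
#' @inheritParams ecs_dissimilarity
#' @return numeric matrix with `labels` (plus "9.9.9") as dimnames.
#' @export
build_ec_matrix <- function(labels, weights = DEFAULT_EC_WEIGHTS) {
  check_weights(weights)
  if (anyDuplicated(labels)) {
    stop(sprintf("duplicate EC label '%s'", labels[duplicated(labels)][1L]),
         call. = FALSE)
  }
  check_scoring_labels(labels)
  labels <- union(labels, EC_UNASSIGNED)
  n <- length(labels)
  S <- matrix(0, n, n, dimnames = list(labels, labels))
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq.int(i + 1L, n)) {
        v <- ec_dissimilarity(labels[i], labels[j], weights)
        S[i, j] <- v
        S[j, i] <- v
      }
    }
  }
  S
}

#' Export / import a substitution matrix as tab-separated text
#'
#' A headered labels-by-labels TSV, for inspection and caching.
#'
#' @param S matrix from [build_ec_matrix()].
#' @param path file path.
#' @return `read_ec_matrix` returns the matrix; `write_ec_matrix` returns
#'   `path` invisibly.
#' @export
write_ec_matrix <- function(S, path) {
  utils::write.table(S, path, sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}

#' @rdname write_ec_matrix
#' @export
read_ec_matrix <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1L,
                          check.names = FALSE, stringsAsFactors = FALSE)
  as.matrix(df)
}

# Pair-scoring closure: either a lookup into a precomputed matrix (erroring
# on unknown labels) or on-the-fly computation from the weights.
make_ec_lookup <- function(smat = NULL, weights = DEFAULT_EC_WEIGHTS) {
  if (is.null(smat)) {
    return(function(a, b) ec_dissimilarity(a, b, weights))
  }
  labs <- rownames(smat)
  function(a, b) {
    if (!(a %in% labs)) stop(sprintf("EC label '%s' not in substitution matrix", a),
                             call. = FALSE)
    if (!(b %in% labs)) stop(sprintf("EC label '%s' not in substitution matrix", b),
                             call. = FALSE)
    smat[a, b]
  }
}
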