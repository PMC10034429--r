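#' All-vs-all / database-vs-database ESS alignment
#'
#' Aligns every unordered pair of sequences within one source (no
#' self-pairs) or every cross pair between two sources, keeping pairs whose
#' composite score does not exceed the threshold.  The default threshold
#' 0.27 is the shuffled-null significance rule of thumb (see
#' [threshold_report()]).  Work is partitioned over `nproc` forked workers;
#' the partitioning never changes the emitted set, so results are identical
#' for any worker count.  Results can be streamed to a tab-separated file
#' (`id1`, `id2`, `score`, plus the two gapped sequences when
#' `alignments = TRUE`), sorted by (id1, id2).
#'
#' @param db1 sequence source: a path accepted by [read_sequences()], a
#'   character vector of colon-separated ESS (ids are assigned 1..n), or a
#'   data.frame with `ess_id`/`seq3` columns.
#' @param db2 optional second source; when absent, all-vs-all within `db1`.
#' @param threshold score cutoff in \[0, 1\]; pairs with score <= threshold
#'   are emitted.
#' @param nproc number of worker processes.
#' @param localize apply [localize_trim()] before scoring.
#' @param alignments include the gapped sequences in the output.
#' @param outfile optional path; results are also written as TSV (scores
#'   truncated to 5 decimals, the reporting convention).
#' @param smat optional precomputed substitution matrix; by default one is
#'   built from the EC labels present in the input sources.
#' @param gap gap cost.
#' @param weights EC level weights.
#' @return data.frame with `id1`, `id2`, `score` (and `aln1`, `aln2` when
#'   `alignments = TRUE`), sorted by (id1, id2).
#' @export
dbalign <- function(db1, db2 = NULL, threshold = 0.27, nproc = 1L,
                    localize = FALSE, alignments = FALSE, outfile = NULL,
                    smat = NULL, gap = 1, weights = DEFAULT_EC_WEIGHTS) {
  if (!is.numeric(threshold) || threshold < 0 || threshold > 1) {
    stop("threshold must lie in [0, 1]", call. = FALSE)
  }
  src1 <- normalize_source(db1)
  src2 <- if (is.null(db2)) NULL else normalize_source(db2)

  parsed1 <- lapply(src1$seq3, parse_ess)
  parsed2 <- if (is.null(src2)) parsed1 else lapply(src2$seq3, parse_ess)
  if (is.null(smat)) {
    labels <- unique(c(unlist(parsed1), unlist(parsed2)))
    smat <- build_ec_matrix(labels, weights)
  }

  if (is.null(src2)) {
    n <- nrow(src1)
    if (n < 2L) {
      pairs <- matrix(integer(0L), nrow = 2L)
    } else {
      pairs <- utils::combn(seq_len(n), 2L)
    }
    ids1 <- src1$ess_id
    ids2 <- src1$ess_id
    seqs2 <- parsed1
  } else {
    grid <- expand.grid(i = seq_len(nrow(src1)), j = seq_len(nrow(src2)))
    pairs <- t(as.matrix(grid))
    ids1 <- src1$ess_id
    ids2 <- src2$ess_id
    seqs2 <- parsed2
  }

  eps <- 1e-12
  worker <- function(k) {
    i <- pairs[1L, k]
    j <- pairs[2L, k]
    aln <- nw_align(parsed1[[i]], seqs2[[j]], smat = smat, gap = gap)
    if (localize) aln <- localize_trim(aln, smat = smat)
    if (aln$score > threshold + eps) return(NULL)
    row <- list(id1 = ids1[[i]], id2 = ids2[[j]], score = aln$score)
    if (alignments) {
      row$aln1 <- format_ess(aln$aligned1)
      row$aln2 <- format_ess(aln$aligned2)
    }
    row
  }

  K <- ncol(pairs)
  res <- if (K == 0L) {
    list()
  } else if (nproc > 1L) {
    parallel::mclapply(seq_len(K), worker, mc.cores = nproc)
  } else {
    lapply(seq_len(K), worker)
  }
  res <- res[!vapply(res, is.null, logical(1L))]
  out <- if (length(res) == 0L) {
    if (alignments) {
      data.frame(id1 = integer(0L), id2 = integer(0L), score = numeric(0L),
                 aln1 = character(0L), aln2 = character(0L),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(id1 = integer(0L), id2 = integer(0L), score = numeric(0L))
    }
  } else {
    do.call(rbind, lapply(res, function(r) {
      as.data.frame(r, stringsAsFactors = FALSE)
    }))
  }
  out <- out[order(out$id1, out$id2), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(outfile)) {
    disp <- out
    disp$score <- format_score(out$score)
    utils::write.table(disp, outfile, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  out
}

# Coerce the accepted batch inputs to a data.frame(ess_id, seq3).
normalize_source <- function(x) {
  if (is.data.frame(x)) {
    if (!all(c("ess_id", "seq3") %in% names(x))) {
      stop("sequence data.frame needs columns 'ess_id' and 'seq3'",
           call. = FALSE)
    }
    return(x[, c("ess_id", "seq3")])
  }
  if (is.character(x)) {
    if (length(x) == 1L && file.exists(x)) return(read_sequences(x))
    ok <- tryCatch({
      for (s in x) parse_ess(s)
      TRUE
    }, error = function(e) e)
    if (inherits(ok, "error")) {
      if (length(x) == 1L && !grepl(":", x, fixed = TRUE)) {
        stop(sprintf("cannot read ESS source '%s': not an existing file nor a parseable ESS",
                     x), call. = FALSE)
      }
      stop(ok)
    }
    return(data.frame(ess_id = seq_along(x), seq3 = x,
                      stringsAsFactors = FALSE))
  }
  stop("cannot interpret sequence source", call. = FALSE)
}
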