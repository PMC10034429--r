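#' Shuffle the EC content of an entire ESS database
#'
#' Builds one replicate of the null model used to judge alignment-score
#' significance: all EC tokens of the whole database are pooled, globally
#' permuted, and dealt back into sequences of the original lengths.  The
#' database-wide EC multiset and the per-sequence length histogram are
#' conserved exactly; what is destroyed is the co-occurrence structure
#' within sequences (a per-sequence permutation would leave each sequence's
#' own composition — and hence family signal — intact, which is why the
#' shuffle is global).
#'
#' @param seqs character vector of colon-separated ESS strings.
#' @param seed integer seed; the same seed reproduces the same shuffle.
#' @return character vector of shuffled ESS strings, same lengths.
#' @export
shuffle_ess_db <- function(seqs, seed) {
  if (length(seqs) == 0L) stop("empty ESS database", call. = FALSE)
  toks <- lapply(seqs, parse_ess)
  lens <- lengths(toks)
  pool <- unlist(toks)
  perm <- with_seed(seed, sample(pool, length(pool)))
  ends <- cumsum(lens)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  vapply(seq_along(lens), function(i) {
    format_ess(perm[starts[i]:ends[i]])
  }, character(1L))
}

#' Null-ensemble significance report for ESS alignment scores
#'
#' Compares the distribution of real all-vs-all alignment scores with an
#' ensemble of shuffled-database score distributions (default 10
#' replicates) and reports, per replicate, mean +/- SD, together with the
#' full curves needed to audit a significance cutoff: cumulative fraction
#' of real and null pairs at or below each candidate threshold, and the
#' fraction of sequences left without any partner ("loss").  The
#' recommended threshold is the largest candidate at which the real
#' cumulative density strictly exceeds the null-ensemble mean (real
#' structure in excess of chance) while the loss stays below `loss_cap`
#' (default 1%).  The fixed reference cutoff 0.27 — the rule of thumb
#' derived from the KEGG-wide database — is reported alongside for
#' comparison; it is not recomputed here.
#'
#' @param real data.frame with `id1`, `id2`, `score` (e.g. from
#'   [dbalign()] with `threshold = 1`).
#' @param null_scores list of numeric score vectors, one per shuffled
#'   replicate.
#' @param loss_cap maximum tolerated fraction of partnerless sequences.
#' @param grid candidate thresholds.
#' @param reference fixed cutoff reported for comparison.
#' @return object of class `ess_threshold_report`: list with `replicates`
#'   (per-replicate n/mean/sd), `real_mean`, `real_sd`, `curves`
#'   (data.frame `threshold`/`real_cum`/`null_cum`/`loss`), `recommended`
#'   (NA when the real scores are not separable from the null),
#'   `separable`, and `reference`.
#' @export
threshold_report <- function(real, null_scores, loss_cap = 0.01,
                             grid = seq(0, 1, by = 0.005),
                             reference = 0.27) {
  if (!is.data.frame(real) || !all(c("id1", "id2", "score") %in% names(real))) {
    stop("'real' must be a data.frame with id1, id2, score", call. = FALSE)
  }
  if (nrow(real) == 0L || length(null_scores) == 0L) {
    stop("real and null score sets must be non-empty", call. = FALSE)
  }
  rs <- real$score
  reps <- data.frame(
    replicate = seq_along(null_scores),
    n = vapply(null_scores, length, integer(1L)),
    mean = vapply(null_scores, mean, numeric(1L)),
    sd = vapply(null_scores, stats::sd, numeric(1L))
  )
  real_cum <- vapply(grid, function(t) mean(rs <= t), numeric(1L))
  null_cum_mat <- vapply(null_scores, function(x) {
    vapply(grid, function(t) mean(x <= t), numeric(1L))
  }, numeric(length(grid)))
  null_cum <- rowMeans(as.matrix(null_cum_mat))
  ids <- unique(c(real$id1, real$id2))
  loss <- vapply(grid, function(t) {
    hit <- rs <= t
    partnered <- unique(c(real$id1[hit], real$id2[hit]))
    1 - length(partnered) / length(ids)
  }, numeric(1L))
  ok <- real_cum > null_cum & loss < loss_cap
  structure(list(
    replicates = reps,
    real_mean = mean(rs),
    real_sd = stats::sd(rs),
    curves = data.frame(threshold = grid, real_cum = real_cum,
                        null_cum = null_cum, loss = loss),
    recommended = if (any(ok)) max(grid[ok]) else NA_real_,
    separable = any(real_cum > null_cum),
    reference = reference
  ), class = "ess_threshold_report")
}

#' @export
print.ess_threshold_report <- function(x, ...) {
  cat(sprintf("Real scores: mean %.4f +/- %.4f\n", x$real_mean, x$real_sd))
  cat(sprintf("Null ensemble (%d replicates): mean of means %.4f\n",
              nrow(x$replicates), mean(x$replicates$mean)))
  if (is.na(x$recommended)) {
    cat("Real and null score distributions are not separable; no threshold recommended.\n")
  } else {
    cat(sprintf("Recommended threshold: %.3f (reference rule of thumb: %.2f)\n",
                x$recommended, x$reference))
  }
  invisible(x)
}

#' Full significance pipeline on a sequence set
#'
#' Convenience wrapper: all-vs-all scores of the real database, `n_null`
#' shuffled replicates each realigned all-vs-all, then
#' [threshold_report()].  Replicate r is shuffled with seed
#' `base_seed + r`.
#'
#' @param seqs character vector of colon-separated ESS strings.
#' @param n_null number of shuffled replicates.
#' @param base_seed base RNG seed.
#' @param nproc workers passed to [dbalign()].
#' @param ... further arguments to [threshold_report()].
#' @return an `ess_threshold_report`.
#' @export
significance_report <- function(seqs, n_null = 10L, base_seed = 1L,
                                nproc = 1L, ...) {
  labels <- unique(unlist(lapply(seqs, parse_ess)))
  smat <- build_ec_matrix(labels)
  real <- dbalign(seqs, threshold = 1, nproc = nproc, smat = smat)
  null_scores <- lapply(seq_len(n_null), function(r) {
    shuffled <- shuffle_ess_db(seqs, seed = base_seed + r)
    dbalign(shuffled, threshold = 1, nproc = nproc, smat = smat)$score
  })
  threshold_report(real, null_scores, ...)
}
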