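# Needleman-Wunsch alignment and the composite scoring function.

worked_pair <- function() {
  list(e1 = "2.7.1:5.3.1:5.3.1:2.7.1:4.1.2:1.2.1", e2 = "5.3.1:5.3.1:4.2.1")
}

test_that("the glycolysis/IMP example reproduces the reference alignment and score", {
  wp <- worked_pair()
  aln <- nw_align(wp$e1, wp$e2)
  expect_identical(format_ess(aln$aligned1), wp$e1)
  expect_identical(format_ess(aln$aligned2), "-.-.-:5.3.1:5.3.1:-.-.-:4.2.1:-.-.-")
  # H = (1 + 0 + 0 + 1 + 11/26 + 1)/6; GP = (0 + 1/1)/2
  expect_equal(aln$H, (3 + 11 / 26) / 6, tolerance = 1e-12)
  expect_equal(aln$GP, 0.5)
  expect_equal(aln$score, 0.95 * (3 + 11 / 26) / 6 + 0.025, tolerance = 1e-12)
  expect_equal(aln$cost, 3 + 11 / 26, tolerance = 1e-12)
  # printed form truncates to 5 decimals
  expect_output(print(aln), "score = 0.56698", fixed = TRUE)
})

test_that("self-alignment is gapless with zero cost and zero score", {
  set.seed(11)
  for (k in 1:10) {
    x <- random_ess_labels(sample(2:8, 1), tiered_alphabet())
    aln <- nw_align(x, x)
    expect_false(any(aln$aligned1 == EC_GAP))
    expect_false(any(aln$aligned2 == EC_GAP))
    expect_equal(aln$cost, 0)
    expect_equal(aln$score, 0)
  }
})

test_that("alignment score is symmetric and removing gaps recovers the inputs", {
  set.seed(12)
  for (k in 1:25) {
    x <- random_ess_labels(sample(2:7, 1), tiered_alphabet())
    y <- random_ess_labels(sample(2:7, 1), tiered_alphabet())
    axy <- nw_align(x, y)
    ayx <- nw_align(y, x)
    expect_equal(axy$score, ayx$score, tolerance = 1e-12)
    expect_equal(axy$cost, ayx$cost, tolerance = 1e-12)
    expect_identical(axy$aligned1[axy$aligned1 != EC_GAP], x)
    expect_identical(axy$aligned2[axy$aligned2 != EC_GAP], y)
    # no gap-vs-gap columns; score components bounded
    expect_false(any(axy$aligned1 == EC_GAP & axy$aligned2 == EC_GAP))
    expect_true(axy$H >= 0 && axy$H <= 1)
    expect_true(axy$GP >= 0 && axy$GP <= 1)
    expect_true(axy$score >= 0 && axy$score <= 1)
    expect_lte(axy$cost, (length(x) + length(y)) * 1)
  }
})

test_that("optimal cost matches naive enumeration on random small instances", {
  smat <- build_ec_matrix(tiered_alphabet())
  lookup <- function(a, b) smat[a, b]
  set.seed(13)
  for (k in 1:40) {
    x <- random_ess_labels(sample(2:4, 1), tiered_alphabet())
    y <- random_ess_labels(sample(2:4, 1), tiered_alphabet())
    expect_equal(nw_align(x, y, smat = smat)$cost,
                 brute_align_cost(x, y, lookup), tolerance = 1e-12)
  }
})

test_that("degenerate substitution limits obey closed forms", {
  labs <- tiered_alphabet()
  zero <- matrix(0, length(labs), length(labs), dimnames = list(labs, labs))
  set.seed(14)
  for (k in 1:10) {
    x <- random_ess_labels(sample(2:6, 1), labs)
    y <- random_ess_labels(sample(2:6, 1), labs)
    expect_equal(nw_align(x, y, smat = zero)$cost,
                 abs(length(x) - length(y)) * 1)
  }
})

test_that("lowering a substitution value never raises the optimal cost", {
  smat <- build_ec_matrix(tiered_alphabet())
  set.seed(15)
  for (k in 1:15) {
    x <- random_ess_labels(4, tiered_alphabet())
    y <- random_ess_labels(5, tiered_alphabet())
    base <- nw_align(x, y, smat = smat)$cost
    a <- sample(rownames(smat), 1)
    b <- sample(rownames(smat), 1)
    low <- smat
    low[a, b] <- low[b, a] <- low[a, b] / 2
    expect_lte(nw_align(x, y, smat = low)$cost, base + 1e-12)
  }
})

test_that("gap penalization counts internal blocks only and tolerates gapless sequences", {
  mk_aln <- function(a1, a2) {
    structure(list(aligned1 = a1, aligned2 = a2, localized = FALSE),
              class = "ess_alignment")
  }
  g <- EC_GAP
  # one internal block of 3 gaps -> 1/3 from that sequence
  a <- mk_aln(c("1.1.1", g, g, g, "2.7.1"), c("1.1.1", "1.2.3", "1.2.9", "1.3.3", "2.7.1"))
  expect_equal(alignment_gap_penalty(a), (1 / 3 + 0) / 2)
  # terminal runs excluded: leading/trailing gaps contribute nothing
  b <- mk_aln(c(g, "1.1.1", "2.7.1", g), c("1.2.3", "1.1.1", "2.7.1", "1.2.9"))
  expect_equal(alignment_gap_penalty(b), 0)
  # two internal singleton blocks: GB/TG = 2/2 = 1
  d <- mk_aln(c("1.1.1", g, "2.7.1", g, "1.2.3"),
              c("1.2.9", "1.1.1", "1.3.3", "2.7.1", "1.2.3"))
  expect_equal(alignment_gap_penalty(d), 0.5)
  # gap columns (terminal included) still score 1 in the homogeneity
  expect_equal(alignment_homogeneity(b),
               (1 + 0 + 0 + 1) / 4)
})

test_that("localize trims to the shorter sequence's span and rescores", {
  wp <- worked_pair()
  aln <- nw_align(wp$e1, wp$e2)
  trim <- localize_trim(aln)
  expect_identical(format_ess(trim$aligned2), "5.3.1:5.3.1:-.-.-:4.2.1")
  expect_identical(format_ess(trim$aligned1), "5.3.1:5.3.1:2.7.1:4.1.2")
  expect_equal(trim$H, (1 + 11 / 26) / 4, tolerance = 1e-12)
  expect_equal(trim$GP, 0.5)
  expect_equal(trim$score, 0.95 * (1 + 11 / 26) / 4 + 0.025, tolerance = 1e-12)
  expect_true(trim$localized)
  # when the shorter ESS spans all columns the trim is the identity
  id <- nw_align("1.2.3:2.7.1", "1.2.3:2.7.1")
  trim_id <- localize_trim(id)
  expect_identical(trim_id$aligned1, id$aligned1)
  expect_equal(trim_id$score, id$score)
})

test_that("fully mismatched gapless alignments score 0.95", {
  aln <- nw_align(c("1.1.1", "2.2.2", "3.3.3"), c("4.4.4", "5.5.5", "6.6.6"))
  expect_equal(aln$H, 1)
  expect_equal(aln$GP, 0)
  expect_equal(aln$score, 0.95)
})

test_that("bad inputs fail loudly", {
  expect_error(nw_align("", "1.1.1"), "malformed|empty")
  expect_error(nw_align("1.1.1:bad", "1.1.1"), "malformed EC label 'bad'")
  smat <- build_ec_matrix(c("1.1.1"))
  expect_error(nw_align("2.7.1", "1.1.1", smat = smat), "2.7.1")
})
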