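# Seed finding, gap-filling/extension, edge refinement

test_that("seeds are maximal below-threshold runs of the minimum length", {
  expect_equal(find_seeds(c(T, T, T, F, T, T), 3), data.frame(lo = 1L, hi = 3L))
  expect_equal(find_seeds(c(T, T, T, F, T, T), 2),
               data.frame(lo = c(1L, 5L), hi = c(3L, 6L)))
  expect_equal(nrow(find_seeds(rep(FALSE, 6), 2)), 0)
})

test_that("undefined windows break runs and are never part of a seed", {
  expect_equal(nrow(find_seeds(c(T, T, NA, T, T), 3)), 0)
  expect_equal(find_seeds(c(T, T, T, NA, T, T, T), 3),
               data.frame(lo = c(1L, 5L), hi = c(3L, 7L)))
})

test_that("gap-filling merges seeds across short above-threshold gaps", {
  below <- c(T, T, T, F, F, T, T, T)
  s <- find_seeds(below, 3)
  expect_equal(fill_and_extend(s, below, 2), data.frame(lo = 1L, hi = 8L))
  # a gap of three is not bridged
  below2 <- c(T, T, T, F, F, F, T, T, T)
  s2 <- find_seeds(below2, 3)
  expect_equal(fill_and_extend(s2, below2, 2), s2)
  # undefined windows inside a gap block merging
  below3 <- c(T, T, T, NA, F, T, T, T)
  s3 <- find_seeds(below3, 3)
  expect_equal(fill_and_extend(s3, below3, 2), s3)
})

test_that("seed extension skips a short flank and appends the following run", {
  # seed at 4-10 (1-based), gap at 11, below at 12-13
  below <- c(F, F, F, T, T, T, T, T, T, T, F, T, T, F)
  s <- find_seeds(below, 3)
  expect_equal(s, data.frame(lo = 4L, hi = 10L))
  expect_equal(fill_and_extend(s, below, 1), data.frame(lo = 4L, hi = 13L))
  # with max_gap 0 nothing is skipped
  expect_equal(fill_and_extend(s, below, 0), s)
})

test_that("extension is one-shot: it does not chain through the background", {
  # seed, then repeated [gap, single below] motifs; one extension allowed
  below <- c(T, T, T, F, T, F, T, F, T, F, T)
  s <- find_seeds(below, 3)
  out <- fill_and_extend(s, below, 2)
  expect_equal(out, data.frame(lo = 1L, hi = 5L))
})

test_that("fill_and_extend never shrinks seeds; output is sorted disjoint", {
  set.seed(21)
  for (rep in 1:80) {
    below <- sample(c(TRUE, FALSE, NA), 60, replace = TRUE,
                    prob = c(0.4, 0.5, 0.1))
    s <- find_seeds(below, 2)
    out <- fill_and_extend(s, below, 2)
    if (nrow(s) == 0) {
      expect_equal(nrow(out), 0)
      next
    }
    for (i in seq_len(nrow(s)))
      expect_true(any(out$lo <= s$lo[i] & out$hi >= s$hi[i]))
    if (nrow(out) > 1) {
      expect_true(all(diff(out$lo) > 0))
      expect_true(all(utils::head(out$hi, -1) < utils::tail(out$lo, -1)))
    }
  }
})

test_that("edges move to the outermost flagged sites of the edge windows", {
  # two windows of 5 markers each covering 1.2-59 Mb
  wc <- data.frame(window = 1:2, chrom = "1", marker_lo = c(1L, 6L),
                   marker_hi = c(5L, 10L))
  pos <- c(1.2e6, 2.0e6, 3.4e6, 4.0e6, 5.0e6,
           56e6, 57e6, 58e6, 58.5e6, 59e6)
  flags <- rep(FALSE, 10)
  flags[c(1, 3)] <- TRUE        # first window flagged at 1.2 and 3.4 Mb
  flags[c(8, 10)] <- TRUE       # last window flagged at 58 and 59 Mb
  bp <- refine_edges(data.frame(lo = 1L, hi = 2L), wc, flags, pos)
  expect_equal(bp, c(3.4e6, 58e6))
})

test_that("without flagged sites the window bounds are kept", {
  wc <- data.frame(window = 1:2, chrom = "1", marker_lo = c(1L, 4L),
                   marker_hi = c(3L, 6L))
  pos <- c(1e6, 2e6, 3e6, 10e6, 11e6, 12e6)
  bp <- refine_edges(data.frame(lo = 1L, hi = 2L), wc, rep(FALSE, 6), pos)
  expect_equal(bp, c(1e6, 12e6))
})

test_that("a single-window seed is kept only when start precedes end", {
  wc <- data.frame(window = 1, chrom = "1", marker_lo = 1L, marker_hi = 6L)
  pos <- seq(1e6, 6e6, by = 1e6)
  seed <- data.frame(lo = 1L, hi = 1L)
  # with flags, start (last flagged) can never precede end (first flagged)
  # within the same window, so the segment degenerates and is dropped
  flags <- c(FALSE, TRUE, FALSE, FALSE, TRUE, FALSE)
  expect_null(refine_edges(seed, wc, flags, pos))
  flags2 <- c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE)
  expect_null(refine_edges(seed, wc, flags2, pos))
  # without flags the window bounds are kept and the seed survives
  expect_equal(refine_edges(seed, wc, rep(FALSE, 6), pos), c(1e6, 6e6))
})

test_that("refined bounds lie within the seed's first and last window spans", {
  set.seed(22)
  for (rep in 1:40) {
    m <- 30
    pos <- sort(sample(1:1e6, m))
    wc <- data.frame(window = 1:3, chrom = "1",
                     marker_lo = c(1L, 11L, 21L), marker_hi = c(10L, 20L, 30L))
    flags <- runif(m) < 0.3
    bp <- refine_edges(data.frame(lo = 1L, hi = 3L), wc, flags, pos)
    if (is.null(bp)) next
    expect_gte(bp[1], pos[1])
    expect_lte(bp[1], pos[10])
    expect_gte(bp[2], pos[21])
    expect_lte(bp[2], pos[30])
  }
})
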