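rpm_track <- function(counts, windows, sample = "s") {
  count_track(counts, windows$index, library_size = 1e6, state = "rpm",
              sample = sample)
}

test_that("log2 ratios follow the pseudocount formula", {
  w <- toy_windows(4)
  a <- rpm_track(c(10, 100, 50, 3), w, "a")
  b <- rpm_track(c(10, 50, 50, 3), w, "b")
  r <- log2_ratio(a, b)
  expect_equal(r$log2_ratio, log2((a$counts + 0.5) / (b$counts + 0.5)))
  expect_equal(r$log2_ratio[c(1, 3, 4)], c(0, 0, 0))
  expect_lt(abs(r$log2_ratio[2] - 1), 0.01)
  expect_equal(r$samples, c("a", "b"))

  set.seed(47)
  x <- rpm_track(rpois(200, 60), w <- toy_windows(200))
  y <- rpm_track(rpois(200, 60), w)
  expect_equal(log2_ratio(x, y, pseudocount = 2)$log2_ratio,
               log2((x$counts + 2) / (y$counts + 2)))
  # antisymmetry
  expect_equal(log2_ratio(x, y)$log2_ratio, -log2_ratio(y, x)$log2_ratio)
  expect_error(log2_ratio(x, rpm_track(1:5, toy_windows(5))), "length")
})

test_that("missingness propagates from either input to the ratio", {
  w <- toy_windows(3)
  a <- count_track(c(10, NA, 30), w$index, 100, state = "gc-corrected")
  b <- count_track(c(10, 20, NA), w$index, 100, state = "gc-corrected")
  r <- log2_ratio(a, b)
  expect_equal(is.na(r$log2_ratio), c(FALSE, TRUE, TRUE))
})

test_that("threshold-run segmentation follows the stated run rules", {
  w <- toy_windows(20)
  L <- rep(0, 20); L[6:11] <- 0.20        # windows 5..10 (0-based)
  r <- structure(list(window_ids = w$index, log2_ratio = L,
                      samples = c("a", "b")), class = "ratio_track")
  seg <- segment_differential(r, w, threshold = 0.10)
  expect_equal(nrow(seg), 1L)
  expect_equal(seg$direction, "gain")
  expect_equal(seg$start, w$start[6])
  expect_equal(seg$end, w$end[11])
  expect_equal(seg$n_windows, 6L)
  expect_equal(seg$mean_ratio, 0.20)

  # all-null track: no segments
  r0 <- structure(list(window_ids = w$index, log2_ratio = rep(0, 20),
                       samples = c("a", "b")), class = "ratio_track")
  expect_equal(nrow(segment_differential(r0, w)), 0L)

  # alternating up/down deviant windows never chain into a segment
  La <- rep(c(0.3, -0.3), 10)
  ra <- structure(list(window_ids = w$index, log2_ratio = La,
                       samples = c("a", "b")), class = "ratio_track")
  expect_equal(nrow(segment_differential(ra, w, min_windows = 3, max_gap = 1)),
               0L)
})

test_that("gap tolerance merges runs but opposite directions split them", {
  w <- toy_windows(12)
  L <- rep(0, 12)
  L[c(2, 3, 5, 6)] <- 0.3                 # one non-deviant gap at 4
  r <- structure(list(window_ids = w$index, log2_ratio = L,
                      samples = c("a", "b")), class = "ratio_track")
  seg <- segment_differential(r, w, min_windows = 3, max_gap = 1)
  expect_equal(nrow(seg), 1L)
  expect_equal(seg$n_windows, 4L)

  # gap of 2 exceeds max_gap = 1: runs of 2 remain below min_windows
  L2 <- rep(0, 12); L2[c(2, 3, 6, 7)] <- 0.3
  r2 <- structure(list(window_ids = w$index, log2_ratio = L2,
                       samples = c("a", "b")), class = "ratio_track")
  expect_equal(nrow(segment_differential(r2, w, min_windows = 3, max_gap = 1)),
               0L)

  # an opposite-direction window inside the gap splits the run
  L3 <- rep(0, 12); L3[c(2, 3, 5, 6)] <- 0.3; L3[4] <- -0.3
  r3 <- structure(list(window_ids = w$index, log2_ratio = L3,
                       samples = c("a", "b")), class = "ratio_track")
  expect_equal(nrow(segment_differential(r3, w, min_windows = 2, max_gap = 1)),
               2L)
})

test_that("raising the threshold never increases the affected extent", {
  set.seed(53)
  w <- toy_windows(400)
  L <- rnorm(400, 0, 0.15)
  L[50:80] <- L[50:80] + 0.35
  r <- structure(list(window_ids = w$index, log2_ratio = L,
                      samples = c("a", "b")), class = "ratio_track")
  mb <- vapply(c(0.05, 0.10, 0.15, 0.25, 0.40), function(th) {
    total_affected_mb(segment_differential(r, w, threshold = th))
  }, numeric(1))
  expect_true(all(diff(mb) <= 0))
})

test_that("affected megabases sum segment spans", {
  w <- toy_windows(10)
  r <- structure(list(window_ids = w$index,
                      log2_ratio = c(rep(0.5, 5), rep(0, 5)),
                      samples = c("a", "b")), class = "ratio_track")
  seg <- segment_differential(r, w)
  expect_equal(total_affected_mb(seg), sum(seg$end - seg$start) / 1e6)
  expect_equal(total_affected_mb(seg[0, ]), 0)

  one <- data.table::data.table(chrom = "chr1", start = 0L, end = 2000000L,
                                n_windows = 10L, mean_ratio = 0.3,
                                direction = "gain")
  expect_equal(total_affected_mb(one), 2)
})

test_that("a clearly separated planted effect is recovered end to end", {
  # planted 1.25 copy factor at threshold 0.10: interior of the detectable
  # region, so segmentation recovers the span with high overlap
  set.seed(59)
  n <- 400; reg <- 151:175
  mu <- rep(500, n); muA <- mu; muA[reg] <- muA[reg] * 1.25
  w <- toy_windows(n)
  a <- rpm_track(rpois(n, muA), w, "cnv")
  b <- rpm_track(rpois(n, mu), w, "ref")
  seg <- segment_differential(log2_ratio(a, b), w, threshold = 0.10)
  gain <- seg[seg$direction == "gain", ]
  expect_gte(nrow(gain), 1L)
  truth <- c(w$start[reg[1]], w$end[reg[length(reg)]])
  inter <- sum(pmax(0, pmin(gain$end, truth[2]) - pmax(gain$start, truth[1])))
  union <- sum(gain$end - gain$start) + (truth[2] - truth[1]) - inter
  expect_gte(inter / union, 0.8)
})
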