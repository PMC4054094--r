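test_that("reads are assigned to windows by half-open start position", {
  w <- toy_windows(2, span = 20000L)
  rs <- read_set(rep("chr1", 3), c(0, 19999, 20000))
  tr <- count_reads(w, rs)
  expect_equal(tr$counts, c(2, 1))
  expect_equal(tr$state, "raw")
  expect_equal(attr(tr, "discarded"), 0L)

  tr0 <- count_reads(w, read_set(character(0), integer(0)))
  expect_equal(tr0$counts, c(0, 0))
})

test_that("duplicate-flagged reads are excluded from counts and library size", {
  w <- toy_windows(2, span = 1000L)
  rs <- read_set(rep("chr1", 4), c(10, 20, 1500, 1600),
                 dup = c(FALSE, TRUE, FALSE, FALSE))
  expect_equal(total_mapped(rs), 3L)
  tr <- count_reads(w, rs)
  expect_equal(tr$counts, c(1, 2))
  expect_equal(tr$library_size, 3)
})

test_that("counting conserves reads and matches the linear-scan oracle", {
  set.seed(11)
  g <- random_genome(50000, n_runs = 2, run_len = 100)
  m <- build_mask(g, random_intervals(50000, 30, max_w = 200))
  w <- partition_accessible(m, 5000)
  pos <- sample.int(50000, 10000, replace = TRUE) - 1L
  rs <- read_set(rep("chr1", length(pos)), pos)
  tr <- count_reads(w, rs)
  o <- oracle_count(w$start, w$end, pos)
  expect_equal(tr$counts, as.numeric(o$counts))
  expect_equal(attr(tr, "discarded"), o$discarded)
  expect_equal(sum(tr$counts) + attr(tr, "discarded"), length(pos))
})

test_that("counting rejects reads on chromosomes outside the window set", {
  w <- toy_windows(2, span = 1000L)
  expect_error(count_reads(w, read_set("chrX", 5)), "chrX")
})

test_that("rpm normalization scales counts per million mapped reads", {
  w <- toy_windows(2, span = 1000L)
  tr <- count_track(c(10, 7), w$index, library_size = 1e6, state = "raw")
  rpm <- rpm_normalize(tr)
  expect_equal(rpm$counts, c(10, 7))
  expect_equal(rpm$state, "rpm")

  tr2 <- count_track(c(7, 0), w$index, library_size = 7e6, state = "raw")
  expect_equal(rpm_normalize(tr2)$counts, c(1, 0))

  set.seed(3)
  cnt <- rpois(50, 40)
  tr3 <- count_track(cnt, seq_len(50) - 1L, library_size = 123457,
                     state = "raw")
  expect_equal(sum(rpm_normalize(tr3)$counts), 1e6 * sum(cnt) / 123457)
  expect_error(rpm_normalize(rpm_normalize(tr3)), "raw")
  expect_error(rpm_normalize(count_track(0, 0L, 0)), "library size")
})

test_that("downsampling is exact, seeded, and boundary cases hold", {
  pos <- sample.int(1e5, 5000)
  rs <- read_set(rep("chr1", 5000), pos, dup = rep(c(FALSE, TRUE), c(4800, 200)))
  d1 <- downsample(rs, 1000, seed = 9)
  d2 <- downsample(rs, 1000, seed = 9)
  expect_identical(as.data.frame(d1), as.data.frame(d2))
  expect_equal(nrow(d1), 1000L)
  expect_true(all(!d1$dup))

  all_of_them <- downsample(rs, 4800, seed = 1)
  expect_equal(sort(all_of_them$pos), sort(rs$pos[!rs$dup]))
  expect_equal(nrow(downsample(rs, 0, seed = 1)), 0L)
  expect_error(downsample(rs, 4801, seed = 1), "4801.*4800")
})

test_that("downsampled window fractions match the hypergeometric expectation", {
  # 10 000 reads split 70/30 over two windows; downsample to 1 000, 200 seeds
  w <- toy_windows(2, span = 10000L)
  pos <- c(sample.int(10000, 7000, replace = TRUE) - 1L,
           sample.int(10000, 3000, replace = TRUE) - 1L + 10000L)
  rs <- read_set(rep("chr1", 10000), pos)
  frac <- vapply(1:200, function(s) {
    d <- downsample(rs, 1000, seed = s)
    count_reads(w, d)$counts[1] / 1000
  }, numeric(1))
  se <- sqrt(0.7 * 0.3 / 1000)  # binomial se per replicate
  expect_lt(abs(mean(frac) - 0.7), 3 * se)
  expect_lt(abs(mean(1 - frac) - 0.3), 3 * se)
})

test_that("quantile normalization equalizes distributions across tracks", {
  w <- toy_windows(3, span = 1000L)
  t1 <- toy_track(c(1, 2, 3), w)
  t2 <- toy_track(c(4, 5, 6), w)
  qn <- quantile_normalize(list(t1, t2))
  expect_equal(qn[[1]]$counts, c(2.5, 3.5, 4.5))
  expect_equal(qn[[2]]$counts, c(2.5, 3.5, 4.5))
  expect_equal(qn[[1]]$state, "quantile")

  same <- quantile_normalize(list(t1, t1))
  expect_equal(same[[1]]$counts, c(1, 2, 3))
})

test_that("quantile normalization matches the naive oracle with ties", {
  set.seed(21)
  w <- toy_windows(100, span = 1000L)
  for (rep in 1:5) {
    mat <- matrix(rpois(400, 30), ncol = 4)   # integer counts: many ties
    tracks <- lapply(1:4, function(j) toy_track(mat[, j], w))
    qn <- quantile_normalize(tracks)
    o <- oracle_quantile(mat)
    for (j in 1:4) expect_equal(qn[[j]]$counts, o[, j])
    # tie-averaging preserves the total mass of the reference distribution,
    # so track sums agree exactly even when tie patterns differ
    for (j in 2:4) expect_equal(sum(qn[[j]]$counts), sum(qn[[1]]$counts))
    # within-track rank order preserved
    for (j in 1:4) {
      expect_true(all(diff(qn[[j]]$counts[order(mat[, j])]) >= 0))
    }
  }
})

test_that("quantile normalization agrees with limma on tie-free data", {
  skip_if_not_installed("limma")
  set.seed(22)
  w <- toy_windows(60, span = 1000L)
  mat <- matrix(rnorm(180, 100, 10), ncol = 3)  # continuous: no ties
  tracks <- lapply(1:3, function(j) {
    count_track(mat[, j], w$index, library_size = 1e6, state = "rpm")
  })
  qn <- quantile_normalize(tracks)
  ref <- limma::normalizeQuantiles(mat)
  for (j in 1:3) expect_equal(qn[[j]]$counts, ref[, j])
  # without ties the output multisets are identical across tracks
  for (j in 2:3) expect_equal(sort(qn[[j]]$counts), sort(qn[[1]]$counts))
})

test_that("quantile normalization rejects mismatched input", {
  w <- toy_windows(3, span = 1000L)
  w2 <- toy_windows(4, span = 1000L)
  expect_error(quantile_normalize(list(toy_track(1:3, w))), "length")
  expect_error(quantile_normalize(list(toy_track(1:3, w),
                                       toy_track(1:4, w2))),
               "differ in length")
})
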