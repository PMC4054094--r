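# Smaller-than-default configs keep the simulator tests fast; the full-size
# study conditions are exercised in test-acceptance.R.
small_config <- function(...) {
  args <- list(chrom_lengths = c(chr1 = 2e6), n_gaps = 1L, gap_length = 2e4,
               n_reads = 2e5)
  override <- list(...)
  args[names(override)] <- override
  do.call(sim_config, args)
}

test_that("genome simulation is deterministic and respects its dials", {
  cfg <- small_config(seed = 7L)
  s1 <- simulate_genome(cfg)
  s2 <- simulate_genome(cfg)
  expect_identical(as.character(s1$genome), as.character(s2$genome))
  expect_identical(s1$repeats, s2$repeats)

  # no repeats requested -> empty repeat annotation
  s0 <- simulate_genome(small_config(repeat_density = 0, seed = 8L))
  expect_equal(nrow(s0$repeats), 0L)

  # degenerate GC range pins genome-wide GC at 0.5 within sampling error
  sg <- simulate_genome(small_config(gc_range = c(0.5, 0.5), n_gaps = 0L,
                                     seed = 9L))
  freq <- Biostrings::letterFrequency(sg$genome[[1]], c("G", "C"))
  gc <- sum(freq) / 2e6
  expect_lt(abs(gc - 0.5), 3 * sqrt(0.25 / 2e6))
})

test_that("simulated GC tracks have isochore-scale autocorrelation", {
  cfg <- sim_config(chrom_lengths = c(chr1 = 1e7), isochore_scale = 1e6,
                    n_gaps = 0L, seed = 11L)
  s <- simulate_genome(cfg)
  g <- s$gc_target$gc                     # 1 kb resolution
  ac <- function(lag) cor(g[seq_len(length(g) - lag)], g[-seq_len(lag)])
  expect_gt(ac(100), ac(2000))            # 100 kb lag vs 2 Mb lag
  expect_gt(ac(100), 0.5)
})

test_that("compaction tracks respond to divergence and GC coupling", {
  cfg <- small_config(seed = 13L)
  g <- simulate_genome(cfg)
  mask <- build_mask(g$genome, g$repeats)
  w <- annotate_gc(g$genome, partition_accessible(mask, cfg$window_size))

  same <- simulate_compaction(small_config(tissue_divergence = 0, seed = 13L), w)
  expect_equal(same[, 1], same[, 2])

  lo <- simulate_compaction(small_config(tissue_divergence = 0.2, seed = 13L), w)
  hi <- simulate_compaction(small_config(tissue_divergence = 1.5, seed = 13L), w)
  expect_gt(cor(lo[, 1], lo[, 2]), cor(hi[, 1], hi[, 2]))

  coupled <- simulate_compaction(small_config(gc_coupling = 1, seed = 13L), w)
  expect_lt(cor(coupled[, 1], w$gc), 0)
  expect_true(all(coupled >= 0 & coupled <= 1))
})

test_that("unbiased settings give uniform multinomial read placement", {
  cfg <- small_config(beta0 = 0, gc_bias = list(flat = TRUE), seed = 17L)
  g <- simulate_genome(cfg)
  mask <- build_mask(g$genome, g$repeats)
  w <- annotate_gc(g$genome, partition_accessible(mask, cfg$window_size))
  H <- simulate_compaction(cfg, w)
  lib <- simulate_reads(w, H[, 1], tau = 60, cfg, seed = 18L)
  expect_equal(lib$truth$expected_share,
               rep(1 / nrow(w), nrow(w)))
  cnt <- count_reads(w, lib$reads)$counts
  gof <- chisq.test(cnt, p = lib$truth$expected_share)
  expect_gt(gof$p.value, 0.01)
  # reads land inside accessible sequence only
  acc <- mask$accessible$chr1
  inacc <- vapply(lib$reads$pos, function(p) {
    any(acc$start <= p & p < acc$end)
  }, logical(1))
  expect_true(all(inacc))
})

test_that("long lysis erases the chromatin signal in expectation", {
  cfg <- small_config(gc_bias = list(flat = TRUE), beta0 = 1, tau0 = 60,
                      seed = 19L)
  g <- simulate_genome(cfg)
  mask <- build_mask(g$genome, g$repeats)
  w <- annotate_gc(g$genome, partition_accessible(mask, cfg$window_size))
  H <- simulate_compaction(cfg, w)
  short <- simulate_reads(w, H[, 1], tau = 10, cfg, seed = 20L)
  long <- simulate_reads(w, H[, 1], tau = 1e6, cfg, seed = 21L)
  expect_lt(cor(short$truth$expected_count, H[, 1]), -0.8)
  cnt <- count_reads(w, long$reads)$counts
  # beta(tau) -> 0: counts decouple from compaction up to sampling noise
  expect_lt(abs(cor(cnt, H[, 1])), 3 / sqrt(nrow(w)))
})

test_that("planted copy factors shift mean coverage by the planted ratio", {
  cnv <- data.frame(chrom = "chr1", start = 5e5, end = 9e5,
                    copy_factor = 1.10, strain = "mut")
  cfg <- small_config(beta0 = 0, gc_bias = list(flat = TRUE),
                      cnv_list = cnv, strains = c("mut", "wt"),
                      n_reads = 1e6, seed = 23L)
  g <- simulate_genome(cfg)
  mask <- build_mask(g$genome, g$repeats)
  w <- annotate_gc(g$genome, partition_accessible(mask, cfg$window_size))
  H <- simulate_compaction(cfg, w)
  lib <- simulate_reads(w, H[, 1], tau = 60, cfg, strain = "mut", seed = 24L)
  cnt <- count_reads(w, lib$reads)$counts
  inside <- lib$truth$copy_factor > 1.05
  expect_gt(sum(inside), 10)
  ratio <- mean(cnt[inside]) / mean(cnt[!inside])
  se <- sqrt(1 / sum(cnt[inside]) + 1 / sum(cnt[!inside])) * 1.10
  expect_lt(abs(ratio - 1.10), 3 * se)
})

test_that("bias strength is identifiable from simulated counts", {
  # regression of log expected count on compaction recovers -beta within 10%
  cfg <- sim_config(chrom_lengths = c(chr1 = 6e6), gc_bias = list(flat = TRUE),
                    beta0 = 0.6, tau0 = Inf, gc_coupling = 0, seed = 29L)
  g <- simulate_genome(cfg)
  mask <- build_mask(g$genome, g$repeats)
  w <- annotate_gc(g$genome, partition_accessible(mask, cfg$window_size))
  H <- simulate_compaction(cfg, w)
  lib <- simulate_reads(w, H[, 1], tau = 100, cfg, seed = 30L)
  cnt <- count_reads(w, lib$reads)$counts
  fit <- lm(log(cnt + 0.5) ~ H[, 1])
  expect_lt(abs(unname(coef(fit)[2]) - (-0.6)) / 0.6, 0.10)
})

test_that("whole-study simulation is reproducible given the config seed", {
  cfg <- preset_config("tiny")
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(as.data.frame(s1$windows), as.data.frame(s2$windows))
  expect_identical(lapply(s1$libraries, function(l) as.data.frame(l$reads)),
                   lapply(s2$libraries, function(l) as.data.frame(l$reads)))
})

test_that("presets encode their scenario contracts", {
  expect_error(preset_config("nope"), "tiny, gc-only")
  expect_equal(preset_config("lysis-series")$lysis_times,
               c(10, 30, 60, 120, 1440))
  tiny <- preset_config("tiny")
  expect_lte(sum(tiny$chrom_lengths), 2.5e6)
  cnv <- preset_config("two-strain-cnv")
  expect_true(all(cnv$cnv_list$copy_factor > 0))
  expect_true(all(cnv$cnv_list$strain %in% cnv$strains))
})
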