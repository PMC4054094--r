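#' Fixture presets
#'
#' Named simulation scenarios used throughout the test suite and examples.
#' Each preset is a fully specified [sim_config()]:
#'
#' * `tiny` — 2 Mb genome, two tissues, two lysis times; end-to-end smoke
#'   scenario that builds in seconds.
#' * `gc-only` — GC bias on, chromatin bias off (`beta0 = 0`); isolates the
#'   GC-correction problem.
#' * `chromatin-only` — flat GC curve, constant chromatin bias
#'   (`beta = 0.5` at every lysis time), compaction independent of GC;
#'   isolates the tissue-specific retrieval bias that GC correction cannot
#'   remove.
#' * `lysis-series` — the proteinase K time series: one library per lysis
#'   duration in 10, 30, 60, 120 and 1440 min (overnight) for each of two
#'   tissues, with chromatin bias decaying over lysis time.
#' * `two-strain-cnv` — unbiased retrieval, two strains, planted germline
#'   CNVs; exercises differential segmentation against known truth.
#'
#' @param preset Preset name.
#' @return A [sim_config()].
#' @export
preset_config <- function(preset = c("tiny", "gc-only", "chromatin-only",
                                     "lysis-series", "two-strain-cnv")) {
  if (!is.character(preset) || !preset[1] %in%
      c("tiny", "gc-only", "chromatin-only", "lysis-series", "two-strain-cnv")) {
    abort("unknown preset '%s'; available: tiny, gc-only, chromatin-only, lysis-series, two-strain-cnv",
          as.character(preset[1]))
  }
  preset <- match.arg(preset)
  switch(preset,
    "tiny" = sim_config(
      chrom_lengths = c(chr1 = 15e5, chr2 = 8e5),
      n_gaps = 1L, gap_length = 2e4,
      lysis_times = c(30, 1440),
      n_reads = 2e5,
      seed = 101L),
    "gc-only" = sim_config(
      beta0 = 0, tissues = "tissueA", tissue_divergence = 0,
      lysis_times = 120,
      seed = 202L),
    "chromatin-only" = sim_config(
      gc_bias = list(flat = TRUE),
      beta0 = 0.5, tau0 = Inf, gc_coupling = 0,
      lysis_times = 120,
      seed = 303L),
    "lysis-series" = sim_config(seed = 404L),
    "two-strain-cnv" = sim_config(
      gc_bias = list(flat = TRUE), beta0 = 0,
      tissues = "liver", tissue_divergence = 0,
      lysis_times = 120,
      strains = c("strainA", "strainB"),
      cnv_list = data.frame(
        chrom = c("chr1", "chr2"),
        start = c(2e6, 1e6), end = c(24e5, 12e5),
        copy_factor = c(1.25, 0.75),
        strain = "strainA"),
      seed = 505L))
}

#' Simulate a full study scenario in memory
#'
#' Runs the whole generator for a preset (or custom config): genome, mask,
#' GC-annotated windows, per-tissue compaction, and one read library per
#' (strain, tissue, lysis time) combination.
#'
#' @param config A [sim_config()], e.g. from [preset_config()].
#' @return List with `config`, `genome`, `repeats`, `mask`, `windows`,
#'   `compaction` (matrix) and `libraries` (named list; each element has
#'   `reads`, `truth`, `tau`, `strain`, `tissue`).
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  sim <- simulate_genome(config)
  mask <- build_mask(sim$genome, sim$repeats)
  windows <- annotate_gc(sim$genome,
                         partition_accessible(mask, config$window_size))
  H <- simulate_compaction(config, windows)
  libs <- list()
  i <- 0L
  for (strain in config$strains) {
    for (tissue in config$tissues) {
      for (tau in config$lysis_times) {
        i <- i + 1L
        lib <- simulate_reads(windows, H[, tissue], tau, config,
                              strain = strain,
                              seed = config$seed + 100L + 2L * i)
        lib$tissue <- tissue
        nm <- sprintf("%s_%s_tau%g", strain, tissue, tau)
        libs[[nm]] <- lib
      }
    }
  }
  list(config = config, genome = sim$genome, repeats = sim$repeats,
       mask = mask, windows = windows, compaction = H, libraries = libs)
}

#' Write a fixture suite to disk
#'
#' Materializes a preset as a file tree: `genome.fa`, `repeats.bed`,
#' `windows.tsv`, `compaction.tsv`, one `reads/<library>.bed` and
#' `truth/<library>.tsv` per library, and a `manifest.yaml` listing every
#' file with its MD5 hash. Output is byte-identical across runs for the same
#' preset and seed.
#'
#' @param preset Preset name (see [preset_config()]).
#' @param outdir Output directory (created).
#' @param seed Optional override of the preset's base seed.
#' @return Path to the manifest, invisibly.
#' @export
make_fixture_suite <- function(preset, outdir, seed = NULL) {
  config <- preset_config(preset)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(outdir, "reads"), showWarnings = FALSE)
  dir.create(file.path(outdir, "truth"), showWarnings = FALSE)
  study <- simulate_study(config)
  files <- character(0)
  fa <- file.path(outdir, "genome.fa")
  Biostrings::writeXStringSet(study$genome, fa)
  files <- c(files, fa)
  rb <- file.path(outdir, "repeats.bed")
  write_bed(study$repeats, rb)
  files <- c(files, rb)
  wt <- file.path(outdir, "windows.tsv")
  write_windows(study$windows, wt)
  files <- c(files, wt)
  ct <- file.path(outdir, "compaction.tsv")
  write_tsv_commented(
    data.table::data.table(window = study$windows$index,
                           study$compaction),
    ct, params = list(preset = preset))
  files <- c(files, ct)
  for (nm in names(study$libraries)) {
    lib <- study$libraries[[nm]]
    rp <- file.path(outdir, "reads", paste0(nm, ".bed"))
    write_bed(data.table::data.table(chrom = lib$reads$chrom,
                                     start = lib$reads$pos,
                                     end = lib$reads$pos + 1L), rp)
    tp <- file.path(outdir, "truth", paste0(nm, ".tsv"))
    write_tsv_commented(lib$truth, tp,
                        params = list(library = nm, tau = lib$tau,
                                      strain = lib$strain,
                                      tissue = lib$tissue))
    files <- c(files, rp, tp)
  }
  manifest <- list(
    preset = preset,
    covbias_version = as.character(packageVersion("covbias")),
    seed = config$seed,
    n_libraries = length(study$libraries),
    files = lapply(setNames(files, sub(paste0("^", outdir, "/?"), "", files)),
                   function(f) unname(tools::md5sum(f))))
  mp <- file.path(outdir, "manifest.yaml")
  yaml::write_yaml(manifest, mp)
  invisible(mp)
}
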