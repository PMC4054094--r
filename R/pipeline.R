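#' Pipeline configuration
#'
#' Reads a YAML pipeline configuration (or accepts an equivalent list):
#'
#' ```yaml
#' genome: ref.fa
#' repeats: rpt.bed          # optional; omit for gaps-only masking
#' mode: accessible          # accessible | span
#' size: 20000
#' reads:
#'   liver: liver.bed
#'   brain: brain.bed
#' downsample_to: 0          # 0 = min library size; omit to skip
#' k: 100                    # GC-correction neighbors
#' threshold: 0.10           # segmentation
#' min_windows: 3
#' max_gap: 1
#' bin_width: 10
#' features:                 # optional; .bedgraph -> signal, else intervals
#'   timing: timing.bedgraph
#'   sine: sine.bed
#' seed: 1
#' out_dir: results
#' ```
#'
#' @param config Path to a YAML file or a named list with the fields above.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  defaults <- list(mode = "accessible", size = 20000L, k = 100L,
                   threshold = 0.10, min_windows = 3L, max_gap = 1L,
                   bin_width = 10, seed = 1L, features = list(),
                   repeats = NULL, downsample_to = NULL)
  for (nm in names(defaults)) {
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  }
  for (nm in c("genome", "reads", "out_dir")) {
    if (is.null(config[[nm]])) abort("pipeline config missing field '%s'", nm)
  }
  for (p in c(config$genome, config$repeats, unlist(config$reads),
              unlist(config$features))) {
    if (!file.exists(p)) abort("pipeline input does not exist: %s", p)
  }
  structure(config, class = c("pipeline_config", "list"))
}

pipe_log <- function(state, fmt, ...) {
  line <- sprintf(fmt, ...)
  message("[covbias] ", line)
  cat(line, "\n", file = state$log, sep = "", append = TRUE)
}

# stage cache: reuse the stored result when the input/parameter hash matches
stage_cached <- function(state, name, hash_of, compute) {
  digest <- paste(unlist(hash_of), collapse = "|")
  hashfile <- file.path(state$cache_dir, paste0(name, ".hash"))
  rdsfile <- file.path(state$cache_dir, paste0(name, ".rds"))
  if (file.exists(hashfile) && file.exists(rdsfile) &&
      identical(readLines(hashfile), digest)) {
    pipe_log(state, "stage %s: cached (hash %s)", name, substr(digest, 1, 16))
    return(readRDS(rdsfile))
  }
  res <- compute()
  saveRDS(res, rdsfile)
  writeLines(digest, hashfile)
  pipe_log(state, "stage %s: computed (hash %s)", name, substr(digest, 1, 16))
  res
}

file_hash <- function(path) unname(tools::md5sum(path))

#' Run the full coverage-bias pipeline
#'
#' Orchestrates windowing, counting, depth matching, GC correction, evenness
#' and dispersion metrics, pairwise log2 ratio segmentation and feature
#' correlations, writing every stage's output plus a run log to
#' `config$out_dir`. Stages are cached on input hashes: rerunning with an
#' unchanged configuration reuses stored results and reproduces identical
#' outputs; changing an input or parameter recomputes only stages downstream
#' of it.
#'
#' @param config A [pipeline_config()] (or YAML path / list).
#' @return Invisibly, a list with the computed objects (`windows`, `counts`,
#'   `corrected`, `dispersion`, `segments`, `correlations`).
#' @export
run_pipeline <- function(config) {
  config <- pipeline_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  cache_dir <- file.path(config$out_dir, "cache")
  dir.create(cache_dir, showWarnings = FALSE)
  state <- list(log = file.path(config$out_dir, "run.log"),
                cache_dir = cache_dir)
  cat("", file = state$log)  # truncate
  pipe_log(state, "covbias %s pipeline: %d sample(s), mode=%s size=%d seed=%d",
           as.character(packageVersion("covbias")), length(config$reads),
           config$mode, as.integer(config$size), as.integer(config$seed))

  genome_hash <- file_hash(config$genome)
  rpt_hash <- if (is.null(config$repeats)) "none" else file_hash(config$repeats)
  windows <- stage_cached(state, "windows",
    list(genome_hash, rpt_hash, config$mode, config$size), function() {
      genome <- as_genome(config$genome)
      repeats <- if (is.null(config$repeats)) NULL else read_bed(config$repeats)
      if (config$mode == "accessible") {
        mask <- build_mask(genome, repeats)
        w <- partition_accessible(mask, config$size)
      } else {
        mask <- build_mask(genome, NULL)
        w <- partition_span(mask, config$size)
      }
      annotate_gc(genome, w)
    })
  write_windows(windows, file.path(config$out_dir, "windows.tsv"),
                bed = file.path(config$out_dir, "windows.bed"))
  pipe_log(state, "windows: %d (dropped remainder %0.f bp)", nrow(windows),
           attr(windows, "dropped_bp"))

  samples <- names(config$reads)
  read_hashes <- vapply(unlist(config$reads), file_hash, "")
  raw <- stage_cached(state, "counts",
    list(genome_hash, rpt_hash, config$mode, config$size, read_hashes,
         config$seed, config$downsample_to), function() {
      lapply(setNames(samples, samples), function(s) {
        rs <- read_reads(config$reads[[s]])
        if (!is.null(config$downsample_to)) {
          target <- if (config$downsample_to > 0) config$downsample_to else
            min(vapply(samples, function(x)
              total_mapped(read_reads(config$reads[[x]])), 0L))
          rs <- downsample(rs, target,
                           seed = config$seed + match(s, samples))
        }
        count_reads(windows, rs, sample = s)
      })
    })
  for (s in samples) {
    pipe_log(state, "sample %s: library_size=%0.f discarded=%d", s,
             raw[[s]]$library_size, attr(raw[[s]], "discarded"))
    write_counts(raw[[s]], windows,
                 file.path(config$out_dir, paste0("counts_", s, ".tsv")))
  }

  corrected <- stage_cached(state, "gc_corrected",
    list(genome_hash, rpt_hash, read_hashes, config$size, config$k,
         config$seed, config$downsample_to), function() {
      lapply(raw, gc_correct, windows = windows, k = config$k)
    })
  disp <- list()
  for (s in samples) {
    write_counts(corrected[[s]], windows,
                 file.path(config$out_dir, paste0("corrected_", s, ".tsv")))
    h <- evenness_histogram(corrected[[s]], config$bin_width)
    write_tsv_commented(
      data.table::data.table(bin_start = head(h$bin_edges, -1),
                             bin_end = tail(h$bin_edges, -1),
                             n_windows = h$window_counts),
      file.path(config$out_dir, paste0("evenness_", s, ".tsv")),
      params = list(sample = s, bin_width = config$bin_width))
    disp[[s]] <- dispersion(corrected[[s]])
    pipe_log(state, "sample %s: dispersion sd=%.3f cv=%.4f", s,
             disp[[s]]$sd, disp[[s]]$cv)
  }
  dtab <- data.table::data.table(
    sample = samples,
    sd = vapply(disp, `[[`, 0, "sd"), iqr = vapply(disp, `[[`, 0, "iqr"),
    mad = vapply(disp, `[[`, 0, "mad"), cv = vapply(disp, `[[`, 0, "cv"))
  write_tsv_commented(dtab, file.path(config$out_dir, "dispersion.tsv"))

  segments <- NULL
  if (length(samples) >= 2L) {
    a <- samples[1]; b <- samples[2]
    ratio <- log2_ratio(corrected[[a]], corrected[[b]])
    segments <- segment_differential(ratio, windows,
                                     threshold = config$threshold,
                                     min_windows = config$min_windows,
                                     max_gap = config$max_gap)
    write_tsv_commented(
      data.table::data.table(window = ratio$window_ids,
                             chrom = windows$chrom, start = windows$start,
                             end = windows$end, log2_ratio = ratio$log2_ratio),
      file.path(config$out_dir, sprintf("ratio_%s_vs_%s.tsv", a, b)),
      params = list(a = a, b = b))
    seg_bed <- data.table::data.table(
      chrom = segments$chrom, start = segments$start, end = segments$end,
      name = segments$direction,
      score = round(1000 * abs(segments$mean_ratio)),
      strand = ".")
    write_bed(seg_bed, file.path(config$out_dir, "segments.bed"))
    write_tsv_commented(segments, file.path(config$out_dir, "segments.tsv"),
                        params = list(threshold = config$threshold,
                                      affected_mb = total_affected_mb(segments)))
    pipe_log(state, "segments %s vs %s: %d, total %.3f Mb", a, b,
             nrow(segments), total_affected_mb(segments))
  }

  correlations <- NULL
  if (length(config$features)) {
    feats <- lapply(names(config$features), function(nm) {
      p <- config$features[[nm]]
      if (grepl("\\.(bedgraph|bg)$", p, ignore.case = TRUE)) {
        bin_signal(read_bedgraph(p), windows, feature_name = nm)
      } else {
        bin_intervals(read_bed(p), windows, feature_name = nm)
      }
    })
    correlations <- pearson_panel(corrected[[samples[1]]], feats)
    write_tsv_commented(correlations,
                        file.path(config$out_dir, "correlations.tsv"),
                        params = list(track = samples[1]))
    pipe_log(state, "correlations: %s",
             paste(sprintf("%s r=%.3f", correlations$feature_name,
                           correlations$r), collapse = "; "))
  }
  invisible(list(windows = windows, counts = raw, corrected = corrected,
                 dispersion = dtab, segments = segments,
                 correlations = correlations))
}
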