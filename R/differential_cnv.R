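#' Per-window log2 ratio between two samples
#'
#' `L_i = log2((a_i + pseudocount) / (b_i + pseudocount))` for two
#' depth-normalized tracks over the same window set. The pseudocount (default
#' 0.5) stabilizes ratios at low counts and approximately unbiases the log at
#' Poisson noise. Windows missing in either input are missing in the ratio.
#'
#' @param trackA,trackB [count_track()]s over the same window set, state
#'   `"rpm"`, `"downsampled"`, `"quantile"` or `"gc-corrected"` (raw tracks of
#'   equal library size are accepted as already depth-matched).
#' @param pseudocount Added to both counts before the ratio.
#' @return An object of class `ratio_track`: list with `window_ids`,
#'   `log2_ratio`, `samples` (names of A and B).
#' @export
log2_ratio <- function(trackA, trackB, pseudocount = 0.5) {
  stopifnot(inherits(trackA, "count_track"), inherits(trackB, "count_track"))
  if (length(trackA$counts) != length(trackB$counts)) {
    abort("log2_ratio: tracks differ in length (%d vs %d)",
          length(trackA$counts), length(trackB$counts))
  }
  l <- log2((trackA$counts + pseudocount) / (trackB$counts + pseudocount))
  structure(list(window_ids = trackA$window_ids,
                 log2_ratio = as.numeric(l),
                 samples = c(trackA$sample, trackB$sample)),
            class = "ratio_track")
}

#' @export
print.ratio_track <- function(x, ...) {
  cat(sprintf("ratio_track %s vs %s: %d windows (%d missing)\n",
              x$samples[1], x$samples[2], length(x$log2_ratio),
              sum(is.na(x$log2_ratio))))
  invisible(x)
}

#' Segment a ratio track into regions of differential apparent copy number
#'
#' A window is deviant-up if `2^L_i >= 1 + threshold` and deviant-down if
#' `2^L_i <= 1 - threshold`. Maximal runs of same-direction deviant windows
#' are merged, allowing up to `max_gap` consecutive non-deviant (but never
#' opposite-direction) windows between deviant ones; runs containing at least
#' `min_windows` deviant windows are reported as segments. Segment boundaries
#' snap to the first and last deviant window so the reported extent is
#' conservative. This threshold-run segmenter quantifies how many megabases
#' show an apparent copy number difference of at least `threshold` between
#' two samples.
#'
#' @param ratio A [log2_ratio()] track.
#' @param windows The [window_set] the ratio is aligned to.
#' @param threshold Minimum fractional copy number difference (default 0.10).
#' @param min_windows Minimum deviant windows per segment (default 3).
#' @param max_gap Maximum run of interleaved non-deviant windows (default 1).
#' @return Data.table of class `segment_table`: `chrom`, `start`, `end`,
#'   `n_windows` (deviant windows), `mean_ratio` (mean `L` over deviant
#'   windows), `direction` (`"gain"`/`"loss"`).
#' @export
segment_differential <- function(ratio, windows, threshold = 0.10,
                                 min_windows = 3L, max_gap = 1L) {
  stopifnot(inherits(ratio, "ratio_track"), inherits(windows, "window_set"))
  if (threshold <= 0) abort("threshold must be > 0")
  if (length(ratio$log2_ratio) != nrow(windows)) {
    abort("ratio track not aligned to window set")
  }
  fc <- 2^ratio$log2_ratio
  dir <- integer(length(fc))                       # 0 = non-deviant / missing
  dir[!is.na(fc) & fc >= 1 + threshold] <- 1L
  dir[!is.na(fc) & fc <= 1 - threshold] <- -1L
  segs <- list()
  for (ch in unique(windows$chrom)) {
    rows <- which(windows$chrom == ch)
    dv <- which(dir[rows] != 0L)
    if (!length(dv)) next
    d <- dir[rows][dv]
    # start a new run when direction flips or the non-deviant gap is too long
    brk <- c(TRUE, d[-1] != d[-length(d)] |
                   diff(dv) - 1L > max_gap)
    run <- cumsum(brk)
    for (r in unique(run)) {
      members <- dv[run == r]
      if (length(members) < min_windows) next
      first <- rows[members[1]]
      last <- rows[members[length(members)]]
      segs[[length(segs) + 1L]] <- data.table::data.table(
        chrom = ch,
        start = windows$start[first],
        end = windows$end[last],
        n_windows = length(members),
        mean_ratio = mean(ratio$log2_ratio[rows[members]]),
        direction = if (d[run == r][1] > 0) "gain" else "loss")
    }
  }
  out <- if (length(segs)) data.table::rbindlist(segs) else {
    data.table::data.table(chrom = character(0), start = integer(0),
                           end = integer(0), n_windows = integer(0),
                           mean_ratio = numeric(0), direction = character(0))
  }
  structure(out, class = c("segment_table", class(out)))
}

#' Total genomic extent of differential segments
#'
#' @param segments A `segment_table` from [segment_differential()].
#' @return Total span in Mb: `sum(end - start) / 1e6`.
#' @export
total_affected_mb <- function(segments) {
  if (!nrow(segments)) return(0)
  sum(as.numeric(segments$end - segments$start)) / 1e6
}
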