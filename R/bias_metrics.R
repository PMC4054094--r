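#' Coverage-evenness histogram
#'
#' Histogram of per-window read counts: the x-axis is the number of reads per
#' window, the y-axis the number of windows with that many reads. The width
#' of the resulting curve summarizes genome-wide unevenness of coverage
#' ("wave" amplitude); a perfectly even library concentrates all windows in
#' one bin.
#'
#' @param track A [count_track()].
#' @param bin_width Width of count bins (default 10 reads); bin m covers
#'   counts in `[m*bin_width, (m+1)*bin_width)`.
#' @return An object of class `evenness_histogram`: list with `bin_edges`
#'   (left edges plus final right edge), `window_counts`, `n_windows`.
#' @export
evenness_histogram <- function(track, bin_width = 10) {
  stopifnot(inherits(track, "count_track"))
  x <- track$counts[!is.na(track$counts)]
  if (!length(x)) abort("evenness_histogram: empty track")
  if (bin_width < 1) abort("bin_width must be >= 1")
  lo <- floor(min(x) / bin_width)
  hi <- floor(max(x) / bin_width)
  bins <- lo:hi
  counts <- tabulate(floor(x / bin_width) - lo + 1L, nbins = length(bins))
  structure(list(bin_edges = c(bins, hi + 1L) * bin_width,
                 window_counts = counts,
                 n_windows = length(x)),
            class = "evenness_histogram")
}

#' @export
print.evenness_histogram <- function(x, ...) {
  cat(sprintf("evenness_histogram: %d windows in %d bins over [%g, %g)\n",
              x$n_windows, length(x$window_counts),
              min(x$bin_edges), max(x$bin_edges)))
  invisible(x)
}

#' Dispersion statistics of a count track
#'
#' Scalar summaries of the width of the evenness curve: standard deviation,
#' interquartile range, median absolute deviation (unscaled, i.e. the raw
#' median of absolute deviations from the median) and coefficient of
#' variation (sd/mean) of per-window counts. Quantiles use linear
#' interpolation (R type 7) so results are bit-reproducible.
#'
#' @param track A [count_track()].
#' @return A list of class `dispersion_stats` with elements `sd`, `iqr`,
#'   `mad`, `cv`, `mean`, `n`.
#' @export
dispersion <- function(track) {
  stopifnot(inherits(track, "count_track"))
  x <- track$counts[!is.na(track$counts)]
  if (!length(x) || mean(x) <= 0) abort("dispersion: mean count must be > 0")
  structure(list(sd = sd(x),
                 iqr = IQR(x, type = 7),
                 mad = mad(x, constant = 1),
                 cv = sd(x) / mean(x),
                 mean = mean(x),
                 n = length(x)),
            class = "dispersion_stats")
}

#' @export
print.dispersion_stats <- function(x, ...) {
  cat(sprintf("dispersion over %d windows: sd=%.3f iqr=%.3f mad=%.3f cv=%.4f\n",
              x$n, x$sd, x$iqr, x$mad, x$cv))
  invisible(x)
}

#' Histogram of per-window differences between two samples
#'
#' Distribution of `countA - countB` per window, for two depth-matched
#' tracks (downsampled to equal depth or quantile normalized). For libraries
#' from two tissues this is the tissue-difference distribution: the wider it
#' is, the more tissue-specific the retrieval bias.
#'
#' @param trackA,trackB [count_track()]s over the same window set.
#' @param bin_width Width of difference bins.
#' @return An `evenness_histogram` of the differences.
#' @export
difference_distribution <- function(trackA, trackB, bin_width = 10) {
  stopifnot(inherits(trackA, "count_track"), inherits(trackB, "count_track"))
  if (length(trackA$counts) != length(trackB$counts)) {
    abort("difference_distribution: tracks differ in length")
  }
  diff <- trackA$counts - trackB$counts
  x <- diff[!is.na(diff)]
  if (!length(x)) abort("difference_distribution: no paired non-missing windows")
  lo <- floor(min(x) / bin_width)
  hi <- floor(max(x) / bin_width)
  bins <- lo:hi
  counts <- tabulate(floor(x / bin_width) - lo + 1L, nbins = length(bins))
  structure(list(bin_edges = c(bins, hi + 1L) * bin_width,
                 window_counts = counts,
                 n_windows = length(x)),
            class = "evenness_histogram")
}

#' Blockwise median smoothing
#'
#' Reduces an ordered signal (per-probe or per-window, genome order) to one
#' median per non-overlapping block of `k` consecutive values — the display
#' smoothing conventionally applied to aCGH log2 ratio tracks (one dot per
#' block of 100 probes). A terminal block with at least `k/2` values is kept,
#' smaller remainders are dropped. When `chrom` is given, blocks never
#' straddle chromosomes.
#'
#' @param values Numeric vector in genome order.
#' @param k Block size (default 100).
#' @param chrom Optional chromosome label per value.
#' @return Data.table with columns `chrom` (if given), `block`, `from`, `to`
#'   (1-based value indices) and `median`.
#' @export
median_smooth <- function(values, k = 100L, chrom = NULL) {
  if (k < 1) abort("k must be >= 1")
  k <- as.integer(k)
  if (is.null(chrom)) chrom <- rep("all", length(values))
  stopifnot(length(chrom) == length(values))
  res <- lapply(unique(chrom), function(ch) {
    idx <- which(chrom == ch)
    x <- values[idx]
    n_full <- length(x) %/% k
    rem <- length(x) - n_full * k
    n <- n_full + as.integer(rem >= k / 2 && rem > 0)
    if (n == 0L) return(NULL)
    from <- (seq_len(n) - 1L) * k + 1L
    to <- pmin(seq_len(n) * k, length(x))
    data.table::data.table(
      chrom = ch, block = seq_len(n), from = idx[from], to = idx[to],
      median = vapply(seq_len(n),
                      function(b) median(x[from[b]:to[b]], na.rm = TRUE),
                      numeric(1)))
  })
  data.table::rbindlist(res[!vapply(res, is.null, TRUE)])
}
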