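#' GC-bias correction by nearest-GC-neighbor medians
#'
#' Corrects each window's read count against the median count of the `k`
#' windows with most similar GC content:
#'
#' \deqn{N_{corr}(i) = N_{med} \cdot N_{obs}(i) / N_{medGC}(i)}
#'
#' where `N_obs(i)` is the observed count in window i, `N_med` the median
#' count over all usable windows of the library, and `N_medGC(i)` the median
#' count over the `k` windows (including window i itself) with smallest
#' `|gc_j - gc_i|`. Ties in GC distance are broken by genomic proximity
#' (smaller `|j - i|`), then by smaller index, so the correction is fully
#' deterministic. The median of an even-length set is the mean of the two
#' central values.
#'
#' Windows with `NA` GC or `NA` counts are excluded from the neighbor pool
#' and stay `NA` in the output. Windows whose GC-neighborhood median is zero
#' cannot be rescaled; they are set to `NA` and their indices recorded in the
#' `flagged` attribute.
#'
#' The correction recenters counts against their GC stratum and therefore
#' removes any (smooth or not) dependence of expected count on GC; it leaves
#' GC-independent structure — such as chromatin-driven retrieval bias —
#' untouched.
#'
#' @param track A [count_track()] aligned to `windows` (any state but
#'   `"gc-corrected"`).
#' @param windows A [window_set] with GC annotated (see [annotate_gc()]).
#' @param k Number of GC neighbors (default 100).
#' @return A [count_track()] with state `"gc-corrected"`, attributes
#'   `n_med` (the library median), `n_medgc` (per-window neighborhood
#'   medians) and `flagged` (indices, 0-based, of zero-median windows).
#' @export
gc_correct <- function(track, windows, k = 100L) {
  stopifnot(inherits(track, "count_track"), inherits(windows, "window_set"))
  if (length(track$counts) != nrow(windows)) {
    abort("track (%d windows) not aligned to window set (%d windows)",
          length(track$counts), nrow(windows))
  }
  if (k < 1) abort("k must be >= 1")
  usable <- which(!is.na(windows$gc) & !is.na(track$counts))
  if (!length(usable) || all(track$counts[usable] == 0)) {
    abort("gc_correct: all counts are zero or missing")
  }
  if (k > length(usable)) {
    warn("k = %d exceeds usable window count %d; clamped", k, length(usable))
    k <- length(usable)
  }
  k <- as.integer(k)
  gc <- windows$gc[usable]
  cnt <- track$counts[usable]
  n_med <- median(cnt)
  nb_med <- gc_neighbor_medians(gc, cnt, k)
  corr <- rep(NA_real_, nrow(windows))
  corr[usable] <- n_med * cnt / nb_med     # NA where nb_med == 0 (flagged)
  corr[usable][nb_med == 0] <- NA_real_
  flagged <- windows$index[usable][nb_med == 0]
  out <- count_track(corr, track$window_ids, track$library_size,
                     state = "gc-corrected", sample = track$sample)
  medgc <- rep(NA_real_, nrow(windows))
  medgc[usable] <- nb_med
  attr(out, "n_med") <- n_med
  attr(out, "n_medgc") <- medgc
  attr(out, "flagged") <- flagged
  out
}

# Per-window median count over the k GC-nearest windows (self included).
# Neighbor order: (|gc_j - gc_i|, |j - i|, j). Runs in O(n * k) by expanding
# a two-sided frontier in GC-sorted order and resolving boundary ties
# explicitly against the full tie set.
gc_neighbor_medians <- function(gc, cnt, k) {
  n <- length(gc)
  ord <- order(gc)                 # positions in ascending GC
  gcs <- gc[ord]
  pos_in_sorted <- integer(n)
  pos_in_sorted[ord] <- seq_len(n)
  out <- numeric(n)
  for (i in seq_len(n)) {
    p <- pos_in_sorted[i]
    lo <- p; hi <- p                # frontier [lo, hi] in sorted order
    while (hi - lo + 1L < k) {
      dlo <- if (lo > 1L) gcs[p] - gcs[lo - 1L] else Inf
      dhi <- if (hi < n) gcs[hi + 1L] - gcs[p] else Inf
      if (dlo <= dhi) lo <- lo - 1L else hi <- hi + 1L
    }
    # boundary GC distance; all windows at strictly smaller distance are in,
    # ties at the boundary distance compete on (|j - i|, j)
    d <- abs(gcs[lo:hi] - gcs[p])
    dmax <- max(d)
    inner <- ord[(lo:hi)[d < dmax]]
    # all windows anywhere in the genome whose |dgc| equals dmax
    ties <- which(abs(gc - gc[i]) == dmax)
    need <- k - length(inner)
    o <- order(abs(ties - i), ties)
    sel <- c(inner, ties[o][seq_len(need)])
    out[i] <- median(cnt[sel])
  }
  out
}
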