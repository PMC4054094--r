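#' Feature tracks on the window grid
#'
#' A `feature_track` holds one real value per window of a [window_set]:
#' either the fraction of the window span covered by a set of annotation
#' intervals (kind `"interval-coverage"`, e.g. gene or SINE density) or the
#' span-weighted mean of a step signal (kind `"signal-mean"`, e.g.
#' replication timing).
#'
#' @name feature_track
NULL

new_feature_track <- function(values, window_ids, feature_name, kind) {
  structure(list(window_ids = as.integer(window_ids),
                 values = as.numeric(values),
                 feature_name = feature_name, kind = kind),
            class = "feature_track")
}

#' @export
print.feature_track <- function(x, ...) {
  cat(sprintf("feature_track '%s' (%s): %d windows\n",
              x$feature_name, x$kind, length(x$values)))
  invisible(x)
}

#' Bin annotation intervals into window coverage fractions
#'
#' For each window, the fraction of its genomic span covered by the union of
#' the intervals (e.g. SINE density or gene density per window).
#'
#' @param intervals Data.frame with `chrom`, `start`, `end` (0-based
#'   half-open), e.g. from [read_bed()].
#' @param windows A [window_set].
#' @param feature_name Label for the resulting track.
#' @return A [feature_track] of kind `"interval-coverage"` with values in
#'   `[0, 1]`. Intervals on chromosomes absent from the window set produce a
#'   warning and contribute nothing.
#' @export
bin_intervals <- function(intervals, windows, feature_name = "feature") {
  stopifnot(inherits(windows, "window_set"))
  iv <- normalize_intervals(intervals)
  bad <- setdiff(unique(iv$chrom), unique(windows$chrom))
  if (length(bad)) {
    warn("feature intervals on chromosome(s) without windows ignored: %s",
         paste(bad, collapse = ", "))
  }
  vals <- numeric(nrow(windows))
  for (ch in unique(windows$chrom)) {
    rows <- which(windows$chrom == ch)
    sub <- iv[iv$chrom == ch, ]
    if (!nrow(sub)) next
    u <- IRanges::reduce(ir0(sub$start, sub$end))
    win <- ir0(windows$start[rows], windows$end[rows])
    hits <- IRanges::findOverlaps(win, u)
    if (!length(hits)) next
    ovl <- IRanges::width(IRanges::pintersect(win[S4Vectors::queryHits(hits)],
                                              u[S4Vectors::subjectHits(hits)]))
    cov <- tapply(ovl, S4Vectors::queryHits(hits), sum)
    idx <- as.integer(names(cov))
    vals[rows[idx]] <- cov / (windows$end[rows[idx]] - windows$start[rows[idx]])
  }
  new_feature_track(vals, windows$index, feature_name, "interval-coverage")
}

#' Bin a step signal into window means
#'
#' For each window, the span-length-weighted mean of a bedGraph-style step
#' function over the covered part of the window; windows with no signal get
#' `NA`.
#'
#' @param signal Data.frame with `chrom`, `start`, `end`, `value`
#'   (non-overlapping steps), e.g. from [read_bedgraph()].
#' @param windows A [window_set].
#' @param feature_name Label for the resulting track.
#' @return A [feature_track] of kind `"signal-mean"`.
#' @export
bin_signal <- function(signal, windows, feature_name = "signal") {
  stopifnot(inherits(windows, "window_set"),
            all(c("chrom", "start", "end", "value") %in% names(signal)))
  sig <- data.table::as.data.table(signal)
  sig <- sig[order(sig$chrom, sig$start), ]
  for (ch in unique(sig$chrom)) {
    s <- sig[sig$chrom == ch, ]
    if (nrow(s) > 1L && any(s$start[-1] < s$end[-nrow(s)])) {
      abort("overlapping signal steps on %s", ch)
    }
  }
  vals <- rep(NA_real_, nrow(windows))
  for (ch in unique(windows$chrom)) {
    rows <- which(windows$chrom == ch)
    s <- sig[sig$chrom == ch, ]
    if (!nrow(s)) next
    win <- ir0(windows$start[rows], windows$end[rows])
    stp <- ir0(s$start, s$end)
    hits <- IRanges::findOverlaps(win, stp)
    if (!length(hits)) next
    w <- IRanges::width(IRanges::pintersect(win[S4Vectors::queryHits(hits)],
                                            stp[S4Vectors::subjectHits(hits)]))
    v <- s$value[S4Vectors::subjectHits(hits)]
    q <- S4Vectors::queryHits(hits)
    wsum <- tapply(w, q, sum)
    vsum <- tapply(w * v, q, sum)
    idx <- as.integer(names(wsum))
    vals[rows[idx]] <- vsum / wsum
  }
  new_feature_track(vals, windows$index, feature_name, "signal-mean")
}

#' Pearson correlation panel of a track against genome features
#'
#' Pearson correlation between a coverage/ratio track and each feature track,
#' over pairwise-complete windows, with a two-sided p-value from the
#' t-distribution with n - 2 degrees of freedom. The p-values are nominal:
#' adjacent windows are autocorrelated, so they overstate significance and
#' should be read as descriptive only.
#'
#' @param track A [count_track()] or [log2_ratio()] track.
#' @param features List of [feature_track]s (or a single one).
#' @return Data.table with columns `feature_name`, `r`, `n`, `p`.
#' @export
pearson_panel <- function(track, features) {
  x <- if (inherits(track, "ratio_track")) track$log2_ratio else track$counts
  if (inherits(features, "feature_track")) features <- list(features)
  stopifnot(all(vapply(features, inherits, TRUE, "feature_track")))
  rows <- lapply(features, function(f) {
    if (length(f$values) != length(x)) {
      abort("feature '%s' not aligned to track", f$feature_name)
    }
    ok <- !is.na(x) & !is.na(f$values)
    n <- sum(ok)
    if (n < 3L) abort("feature '%s': fewer than 3 paired windows", f$feature_name)
    if (sd(x[ok]) == 0) abort("zero variance in track")
    if (sd(f$values[ok]) == 0) abort("zero variance in feature '%s'", f$feature_name)
    ct <- stats::cor.test(x[ok], f$values[ok], method = "pearson",
                          alternative = "two.sided")
    data.table::data.table(feature_name = f$feature_name,
                           r = unname(ct$estimate), n = n, p = ct$p.value)
  })
  data.table::rbindlist(rows)
}
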