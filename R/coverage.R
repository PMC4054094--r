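#' Read sets
#'
#' A `read_set` holds aligned single-position reads: a table with columns
#' `chrom`, `pos` (0-based start position) and logical `dup` (PCR-duplicate
#' flag). Duplicate-flagged reads are retained in the object but excluded
#' from every analysis, mirroring standard duplicate-marking practice. The
#' library size (`total_mapped`) is the number of non-duplicate reads.
#'
#' @param chrom Character vector of chromosome names.
#' @param pos Integer vector of 0-based read start positions.
#' @param dup Logical duplicate flags (default all `FALSE`).
#' @return An object of class `read_set` (a data.table sorted by
#'   chrom, pos).
#' @export
read_set <- function(chrom, pos, dup = FALSE) {
  stopifnot(length(chrom) == length(pos))
  dt <- data.table::data.table(chrom = as.character(chrom),
                               pos = as.integer(pos),
                               dup = rep_len(as.logical(dup), length(pos)))
  if (anyNA(dt$pos) || any(dt$pos < 0)) abort("read positions must be >= 0")
  dt <- dt[order(dt$chrom, dt$pos), ]
  structure(dt, class = c("read_set", class(dt)))
}

#' Number of non-duplicate reads in a read set
#' @param reads A [read_set()].
#' @return Integer count.
#' @export
total_mapped <- function(reads) {
  stopifnot(inherits(reads, "read_set"))
  sum(!reads$dup)
}

#' @export
print.read_set <- function(x, ...) {
  cat(sprintf("read_set: %d reads (%d non-duplicate) on %d chromosome(s)\n",
              nrow(x), total_mapped(x), length(unique(x$chrom))))
  invisible(x)
}

#' Per-window count tracks
#'
#' A `count_track` pairs a vector of per-window counts with the window ids of
#' a [window_set], the library size and a normalization state, one of
#' `"raw"`, `"rpm"`, `"downsampled"`, `"quantile"`, `"gc-corrected"`.
#' Raw counts are integers; normalized states hold reals. Windows flagged as
#' unusable (e.g. zero GC-neighborhood median) carry `NA`.
#'
#' @param counts Numeric vector of per-window values.
#' @param window_ids Integer window indices (0-based, matching the
#'   `window_set` used to count).
#' @param library_size Total non-duplicate reads in the library.
#' @param state Normalization state.
#' @param sample Sample/library label.
#' @return An object of class `count_track`.
#' @export
count_track <- function(counts, window_ids, library_size,
                        state = c("raw", "rpm", "downsampled", "quantile",
                                  "gc-corrected"),
                        sample = "sample") {
  state <- match.arg(state)
  stopifnot(length(counts) == length(window_ids))
  if (state == "raw") {
    if (any(counts[!is.na(counts)] %% 1 != 0)) abort("raw counts must be integers")
    if (sum(counts, na.rm = TRUE) > library_size) {
      abort("raw counts sum (%s) exceeds library size (%s)",
            format(sum(counts, na.rm = TRUE)), format(library_size))
    }
  }
  if (any(counts[!is.na(counts)] < 0)) abort("counts must be non-negative")
  structure(list(window_ids = as.integer(window_ids),
                 counts = as.numeric(counts),
                 library_size = as.numeric(library_size),
                 state = state, sample = sample),
            class = "count_track")
}

#' @export
print.count_track <- function(x, ...) {
  cat(sprintf("count_track '%s': %d windows, state=%s, library_size=%.0f\n",
              x$sample, length(x$counts), x$state, x$library_size))
  invisible(x)
}

#' Count reads per window
#'
#' Each non-duplicate read is assigned to the unique window whose
#' `[start, end)` span contains its start position. Reads falling outside all
#' window spans (leading/trailing unwindowed sequence) are discarded; their
#' number is recorded in the `discarded` attribute of the result.
#'
#' @param windows A [window_set].
#' @param reads A [read_set()].
#' @param sample Sample label for the resulting track.
#' @return A raw-state [count_track()] with attribute `discarded`.
#' @export
count_reads <- function(windows, reads, sample = "sample") {
  stopifnot(inherits(windows, "window_set"), inherits(reads, "read_set"))
  bad <- setdiff(unique(reads$chrom), unique(windows$chrom))
  if (length(bad)) {
    abort("reads on chromosome(s) absent from window set: %s",
          paste(bad, collapse = ", "))
  }
  keep <- !reads$dup
  counts <- rep.int(0L, nrow(windows))
  discarded <- 0L
  for (chrom in unique(windows$chrom)) {
    rows <- which(windows$chrom == chrom)
    pos <- reads$pos[keep & reads$chrom == chrom]
    if (!length(pos)) next
    # spans abut within a chromosome: locate by window start, then check end
    i <- findInterval(pos, windows$start[rows])
    inside <- i >= 1L & pos < windows$end[rows][pmax(i, 1L)]
    discarded <- discarded + sum(!inside)
    tab <- tabulate(i[inside], nbins = length(rows))
    counts[rows] <- counts[rows] + tab
  }
  tr <- count_track(counts, windows$index, library_size = total_mapped(reads),
                    state = "raw", sample = sample)
  attr(tr, "discarded") <- discarded
  tr
}

#' Reads-per-million normalization
#'
#' Scales raw per-window counts to reads per million sequenced (non-duplicate)
#' reads: `counts * 1e6 / library_size`.
#'
#' @param track A raw-state [count_track()].
#' @return The track with state `"rpm"`.
#' @export
rpm_normalize <- function(track) {
  stopifnot(inherits(track, "count_track"))
  if (track$state != "raw") abort("rpm_normalize expects a raw track, got '%s'", track$state)
  if (track$library_size <= 0) abort("library size must be > 0")
  track$counts <- track$counts * 1e6 / track$library_size
  track$state <- "rpm"
  track
}

#' Randomly downsample a read set to a target depth
#'
#' Draws a uniform random subset (without replacement) of exactly `target`
#' non-duplicate reads, emulating normalization of libraries to a common
#' depth by random removal of reads. Duplicate-flagged reads are dropped.
#'
#' @param reads A [read_set()].
#' @param target Number of reads to keep.
#' @param seed Integer seed (required; the only source of randomness).
#' @return A [read_set()] with `target` reads, none flagged duplicate.
#' @export
downsample <- function(reads, target, seed) {
  stopifnot(inherits(reads, "read_set"))
  n <- total_mapped(reads)
  if (target > n) {
    abort("downsampling target (%d) exceeds non-duplicate reads (%d)",
          as.integer(target), n)
  }
  idx <- which(!reads$dup)
  pick <- local_seed(seed, idx[sample.int(length(idx), size = as.integer(target))])
  read_set(reads$chrom[pick], reads$pos[pick])
}

#' Cross-sample quantile normalization of count tracks
#'
#' Standard rank-based quantile normalization across libraries: per-window
#' counts are ranked within each track, and the value at rank r is replaced by
#' the mean, across tracks, of each track's rank-r value. Tied windows receive
#' the mean of the reference values over their rank range, so output tracks
#' share an identical multiset of values while preserving within-track rank
#' order.
#'
#' @param tracks List of [count_track()]s over the same window set, state
#'   `"raw"` or `"rpm"`.
#' @return List of tracks with state `"quantile"`.
#' @export
quantile_normalize <- function(tracks) {
  stopifnot(is.list(tracks), length(tracks) >= 2L,
            all(vapply(tracks, inherits, TRUE, "count_track")))
  n <- length(tracks[[1]]$counts)
  if (!all(vapply(tracks, function(t) length(t$counts), 0L) == n)) {
    abort("quantile_normalize: tracks differ in length")
  }
  if (!all(vapply(tracks, function(t) t$state, "") %in% c("raw", "rpm"))) {
    abort("quantile_normalize expects raw or rpm tracks")
  }
  ref <- rowMeans(vapply(tracks, function(t) sort(t$counts), numeric(n)))
  lapply(tracks, function(t) {
    ord <- order(t$counts)
    grp <- cumsum(!duplicated(t$counts[ord]))     # tie groups in sorted order
    newv <- ave(ref, grp)[order(ord)]              # mean of ref over rank range
    t$counts <- newv
    t$state <- "quantile"
    t
  })
}

#' @importFrom stats ave
NULL
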