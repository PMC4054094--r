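#' Genomic window sets
#'
#' A `window_set` is a data.frame (one row per window, genome order) with
#' columns `chrom`, `start`, `end` (0-based half-open span), `accessible_bp`
#' (bp of masked-in sequence within the span), `gc` (fraction over accessible
#' unambiguous bases; `NA` until [annotate_gc()] is run or when a window has
#' no unambiguous accessible base) and `index` (0-based ordinal in genome
#' order). The partitioning mode (`"accessible-content"` or `"genomic-span"`),
#' the target size and the mask used are carried as attributes.
#'
#' @name window_set
NULL

new_window_set <- function(df, mode, size, mask) {
  df <- data.table::as.data.table(df)
  df$index <- seq_len(nrow(df)) - 1L
  structure(df, class = c("window_set", class(df)),
            mode = mode, size = size, mask = mask)
}

#' @export
print.window_set <- function(x, ...) {
  cat(sprintf("window_set: %d windows, mode=%s, size=%d bp\n",
              nrow(x), attr(x, "mode"), attr(x, "size")))
  NextMethod()
}

# Core accumulation rule shared by both partition modes: scan accessible
# intervals of one chromosome left to right and cut a window boundary exactly
# when the accumulated accessible bp reaches `size`. Window spans abut: each
# window starts where the previous one ended (the first at the first
# accessible base). The terminal remainder is kept iff >= size/2 accessible bp.
partition_chrom <- function(iv, size) {
  if (nrow(iv) == 0L) {
    return(data.table::data.table(start = integer(0), end = integer(0),
                                  accessible_bp = integer(0)))
  }
  widths <- iv$end - iv$start
  total <- sum(as.numeric(widths))
  n_full <- floor(total / size)
  cum <- cumsum(as.numeric(widths))
  cuts <- size * seq_len(n_full)           # accessible offsets of boundaries
  j <- findInterval(cuts, cum, left.open = TRUE) + 1L  # interval holding cut
  prev_cum <- c(0, cum)[j]
  bound <- iv$start[j] + as.integer(cuts - prev_cum)   # genomic boundary
  starts <- c(iv$start[1], bound)
  ends <- c(bound, iv$end[nrow(iv)])
  acc <- c(rep.int(size, n_full), total - n_full * size)
  keep_tail <- acc[length(acc)] >= size / 2
  n <- n_full + as.integer(keep_tail)
  data.table::data.table(start = starts[seq_len(n)], end = ends[seq_len(n)],
                         accessible_bp = as.integer(acc[seq_len(n)]))
}

partition_windows <- function(mask, size, mode) {
  stopifnot(inherits(mask, "accessibility_mask"))
  if (size < 1) abort("window size must be >= 1 bp")
  size <- as.integer(size)
  per_chrom <- lapply(names(mask$chrom_lengths), function(chrom) {
    w <- partition_chrom(mask$accessible[[chrom]], size)
    if (nrow(w)) w$chrom <- chrom
    w
  })
  df <- data.table::rbindlist(per_chrom[vapply(per_chrom, nrow, 0L) > 0])
  if (nrow(df) == 0L) {
    warn("window size %d exceeds accessible content of every chromosome; empty window set",
         size)
    df <- data.table::data.table(chrom = character(0), start = integer(0),
                                 end = integer(0), accessible_bp = integer(0))
  }
  df <- df[, c("chrom", "start", "end", "accessible_bp")]
  df$gc <- rep(NA_real_, nrow(df))
  dropped <- sum(accessible_bp(mask)) - sum(as.numeric(df$accessible_bp))
  ws <- new_window_set(df, mode, size, mask)
  attr(ws, "dropped_bp") <- dropped
  ws
}

#' Partition a genome into windows of fixed accessible content
#'
#' Each window (except possibly a terminal remainder per chromosome) contains
#' exactly `W` bp of accessible sequence; its genomic span stretches over any
#' interleaved repeats/gaps so that consecutive windows abut. This is the
#' windowing used for fragment-library depth-of-coverage analysis (20 kb of
#' accessible sequence per window by convention).
#'
#' Terminal remainders with at least `W/2` accessible bp are kept; smaller
#' ones are dropped (their size is recorded in the `dropped_bp` attribute).
#'
#' @param mask An [accessibility_mask()] built with repeats and gaps excluded.
#' @param W Accessible bp per window.
#' @return A [window_set] with `gc = NA` (see [annotate_gc()]).
#' @export
partition_accessible <- function(mask, W = 20000L) {
  partition_windows(mask, W, "accessible-content")
}

#' Partition a genome into windows of fixed non-gap span
#'
#' Same accumulation rule as [partition_accessible()], but the mask should
#' exclude assembly gaps only (repeats stay in): each window contains `S` bp
#' of non-gap sequence. This is the windowing used for mate-pair
#' depth-of-coverage analysis (100 kb of genome sequence per window by
#' convention).
#'
#' @param mask An [accessibility_mask()] built with `repeats = NULL`
#'   (gaps-only exclusion).
#' @param S Non-gap bp per window.
#' @return A [window_set].
#' @export
partition_span <- function(mask, S = 100000L) {
  partition_windows(mask, S, "genomic-span")
}

#' Annotate windows with GC content
#'
#' GC is computed over the accessible bases of each window's span:
#' `(#G + #C) / (#A + #C + #G + #T)`, ambiguous bases ignored in the
#' denominator. Windows with zero unambiguous accessible bases get `gc = NA`
#' and are excluded from GC correction downstream.
#'
#' @param genome A [Biostrings::DNAStringSet] or FASTA path.
#' @param windows A [window_set] (carries its mask).
#' @return The `window_set` with the `gc` column filled in.
#' @export
annotate_gc <- function(genome, windows) {
  stopifnot(inherits(windows, "window_set"))
  genome <- as_genome(genome)
  mask <- attr(windows, "mask")
  gc <- rep(NA_real_, nrow(windows))
  for (chrom in unique(windows$chrom)) {
    if (!chrom %in% names(genome)) {
      abort("window chromosome %s absent from genome", chrom)
    }
    rows <- which(windows$chrom == chrom)
    iv <- mask$accessible[[chrom]]
    win <- ir0(windows$start[rows], windows$end[rows])
    acc <- ir0(iv$start, iv$end)
    hits <- IRanges::findOverlaps(win, acc)
    if (length(hits) == 0L) next
    pieces <- IRanges::pintersect(win[S4Vectors::queryHits(hits)],
                                  acc[S4Vectors::subjectHits(hits)])
    v <- Biostrings::Views(genome[[chrom]], pieces)
    freq <- Biostrings::letterFrequency(v, c("A", "C", "G", "T"))
    piece_gc <- freq[, "G"] + freq[, "C"]
    piece_acgt <- rowSums(freq)
    gcsum <- tapply(piece_gc, S4Vectors::queryHits(hits), sum)
    nsum <- tapply(piece_acgt, S4Vectors::queryHits(hits), sum)
    idx <- as.integer(names(gcsum))
    val <- ifelse(nsum > 0, gcsum / nsum, NA_real_)
    gc[rows[idx]] <- val
  }
  windows$gc <- as.numeric(gc)
  windows
}
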