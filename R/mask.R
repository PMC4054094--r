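#' Accessibility masks
#'
#' An `accessibility_mask` records, per chromosome, the intervals of
#' NGS-accessible sequence: everything outside annotated repeats and assembly
#' gaps (maximal runs of `N` bases). All coordinates are 0-based half-open,
#' following the BED convention.
#'
#' @param chrom_lengths Named integer vector of chromosome lengths (bp).
#' @param intervals Named list (one element per chromosome) of data.frames
#'   with columns `start`, `end` (0-based half-open accessible intervals).
#' @return An object of class `accessibility_mask`.
#' @seealso [build_mask()]
#' @export
accessibility_mask <- function(chrom_lengths, intervals) {
  stopifnot(is.numeric(chrom_lengths), !is.null(names(chrom_lengths)),
            is.list(intervals))
  if (!setequal(names(intervals), names(chrom_lengths))) {
    abort("mask intervals and chrom_lengths name different chromosomes")
  }
  intervals <- intervals[names(chrom_lengths)]
  for (chrom in names(chrom_lengths)) {
    iv <- data.table::as.data.table(intervals[[chrom]])
    if (nrow(iv)) {
      iv <- merge_intervals0(iv$start, iv$end)
      if (iv$start[1] < 0L || iv$end[nrow(iv)] > chrom_lengths[[chrom]]) {
        abort("accessible intervals outside [0, %d) on %s",
              chrom_lengths[[chrom]], chrom)
      }
    }
    intervals[[chrom]] <- iv
  }
  structure(list(chrom_lengths = setNames(as.integer(chrom_lengths),
                                          names(chrom_lengths)),
                 accessible = intervals),
            class = "accessibility_mask")
}

#' @export
print.accessibility_mask <- function(x, ...) {
  bp <- vapply(x$accessible, function(iv) sum(iv$end - iv$start), numeric(1))
  cat(sprintf("accessibility_mask: %d chromosome(s), %.0f / %.0f bp accessible\n",
              length(x$chrom_lengths), sum(bp), sum(as.numeric(x$chrom_lengths))))
  invisible(x)
}

#' Total accessible bp per chromosome
#' @param mask An `accessibility_mask`.
#' @return Named numeric vector of accessible bp.
#' @export
accessible_bp <- function(mask) {
  stopifnot(inherits(mask, "accessibility_mask"))
  vapply(mask$accessible, function(iv) sum(as.numeric(iv$end - iv$start)),
         numeric(1))
}

# Maximal runs of N/n in one sequence, as 0-based half-open intervals.
n_runs <- function(seq) {
  m <- Biostrings::matchPattern("N", seq, fixed = TRUE)
  if (length(m) == 0L) {
    return(data.table::data.table(start = integer(0), end = integer(0)))
  }
  dt0(IRanges::reduce(methods::as(m, "IRanges")))
}

#' Build an accessibility mask from a genome and repeat annotation
#'
#' Accessible sequence is the complement of the union of repeat intervals and
#' assembly gaps, where a gap is a maximal run of `N` bases in the sequence.
#' This realizes the "excluding repeats and gaps" rule used when windowing a
#' genome into units of fixed accessible content.
#'
#' @param genome A [Biostrings::DNAStringSet] (named by chromosome) or the
#'   path to a FASTA file.
#' @param repeats Repeat intervals: a data.frame with columns
#'   `chrom`, `start`, `end` (0-based half-open), e.g. from [read_bed()], or
#'   `NULL` for none. In gaps-only mode (see [partition_span()]) pass `NULL`.
#' @return An [accessibility_mask()].
#' @examples
#' g <- Biostrings::DNAStringSet(c(chr1 = "ACGTACGTNNACGTACGT"))
#' m <- build_mask(g, data.frame(chrom = "chr1", start = 0, end = 4))
#' m$accessible$chr1
#' @export
build_mask <- function(genome, repeats = NULL) {
  genome <- as_genome(genome)
  if (length(genome) == 0L) abort("empty genome: no sequences")
  chrom_lengths <- setNames(Biostrings::width(genome), names(genome))
  rpt <- normalize_intervals(repeats)
  bad <- setdiff(unique(rpt$chrom), names(chrom_lengths))
  if (length(bad)) {
    abort("repeat annotation names unknown chromosome(s): %s",
          paste(bad, collapse = ", "))
  }
  if (nrow(rpt)) {
    out <- rpt[rpt$start < 0 | rpt$end > chrom_lengths[rpt$chrom], ]
    if (nrow(out)) {
      abort("repeat interval outside chromosome bounds on %s", out$chrom[1])
    }
  }
  intervals <- lapply(names(chrom_lengths), function(chrom) {
    len <- chrom_lengths[[chrom]]
    excl <- rbind(rpt[rpt$chrom == chrom, c("start", "end")],
                  n_runs(genome[[chrom]]))
    if (nrow(excl) == 0L) {
      return(data.table::data.table(start = 0L, end = len))
    }
    gaps <- IRanges::gaps(IRanges::reduce(ir0(excl$start, excl$end)),
                          start = 1L, end = len)
    dt0(gaps)
  })
  accessibility_mask(chrom_lengths, setNames(intervals, names(chrom_lengths)))
}

# Accepts DNAStringSet or FASTA path; uppercases so N-run detection and GC
# counting are case-insensitive.
as_genome <- function(genome) {
  if (is.character(genome) && length(genome) == 1L) {
    genome <- Biostrings::readDNAStringSet(genome)
    # FASTA headers may carry descriptions; keep the first token
    names(genome) <- sub("\\s.*$", "", names(genome))
  }
  stopifnot(methods::is(genome, "DNAStringSet"))
  if (length(genome) == 0L) abort("empty genome: no sequences")
  if (is.null(names(genome)) || anyDuplicated(names(genome))) {
    abort("genome sequences must have unique names")
  }
  genome
}

# Coerce interval input (NULL / data.frame with chrom,start,end) to a
# data.table with integer 0-based coordinates.
normalize_intervals <- function(x) {
  if (is.null(x) || (is.data.frame(x) && nrow(x) == 0L)) {
    return(data.table::data.table(chrom = character(0), start = integer(0),
                                  end = integer(0)))
  }
  stopifnot(is.data.frame(x), all(c("chrom", "start", "end") %in% names(x)))
  dt <- data.table::data.table(chrom = as.character(x$chrom),
                               start = as.integer(x$start),
                               end = as.integer(x$end))
  if (any(dt$start >= dt$end)) abort("interval with start >= end")
  if (any(dt$start < 0)) abort("interval with negative start")
  dt[order(dt$chrom, dt$start, dt$end), ]
}
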