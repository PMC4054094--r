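# Independent brute-force oracles. These deliberately share no code with the
# package implementations: everything is per-base / per-element scanning.

# per-base boolean accessibility from 0-based half-open exclusion intervals
oracle_accessible <- function(len, excl_start, excl_end) {
  acc <- rep(TRUE, len)
  for (j in seq_along(excl_start)) {
    if (excl_end[j] > excl_start[j]) {
      acc[(excl_start[j] + 1):excl_end[j]] <- FALSE
    }
  }
  acc
}

# per-base scanning partition: cut a boundary exactly when the accumulated
# accessible count reaches W; spans abut; terminal remainder kept iff >= W/2
oracle_partition <- function(acc, W) {
  cum <- cumsum(acc)
  total <- cum[length(cum)]
  if (total == 0) {
    return(data.frame(start = integer(0), end = integer(0),
                      accessible_bp = integer(0)))
  }
  n_full <- total %/% W
  ends <- vapply(seq_len(n_full) * W,
                 function(m) which(cum >= m)[1], integer(1))  # 1-based pos
  first_start <- which(acc)[1] - 1L                            # 0-based
  last_end <- max(which(acc))                                  # 0-based end
  starts <- c(first_start, ends)
  rem <- total - n_full * W
  if (rem >= W / 2 && rem > 0) {
    ends <- c(ends, last_end)
    accs <- c(rep(W, n_full), rem)
  } else {
    accs <- rep(W, n_full)
  }
  n <- length(ends)
  data.frame(start = as.integer(starts[seq_len(n)]),
             end = as.integer(ends),
             accessible_bp = as.integer(accs))
}

# neighbor-sort GC-correction oracle: for each window sort ALL windows by
# (|dGC|, |dindex|, index), take the first k, compute medians independently
oracle_gc_correct <- function(gc, cnt, k) {
  n <- length(gc)
  n_med <- median(cnt)
  medgc <- vapply(seq_len(n), function(i) {
    o <- order(abs(gc - gc[i]), abs(seq_len(n) - i), seq_len(n))
    median(cnt[o[seq_len(k)]])
  }, numeric(1))
  corr <- ifelse(medgc == 0, NA_real_, n_med * cnt / medgc)
  list(corr = corr, medgc = medgc, n_med = n_med)
}

# naive sort-based quantile normalization with mean-over-tied-rank-range
oracle_quantile <- function(mat) {
  ref <- rowMeans(apply(mat, 2, sort))
  out <- mat
  for (j in seq_len(ncol(mat))) {
    x <- mat[, j]
    for (v in unique(x)) {
      at <- which(x == v)
      lo <- sum(x < v) + 1L
      hi <- sum(x <= v)
      out[at, j] <- mean(ref[lo:hi])
    }
  }
  out
}

# per-read linear-scan window assignment
oracle_count <- function(win_start, win_end, pos) {
  counts <- rep(0L, length(win_start))
  discarded <- 0L
  for (p in pos) {
    hit <- which(win_start <= p & p < win_end)
    if (length(hit) == 1L) counts[hit] <- counts[hit] + 1L
    else discarded <- discarded + 1L
  }
  list(counts = counts, discarded = discarded)
}

# random test genome: named DNAStringSet with optional N runs
random_genome <- function(len, n_runs = 0, run_len = 10, name = "chr1") {
  s <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
  if (n_runs > 0) {
    starts <- sample.int(len - run_len, n_runs)
    for (st in starts) s[st:(st + run_len - 1L)] <- "N"
  }
  g <- Biostrings::DNAStringSet(paste(s, collapse = ""))
  names(g) <- name
  g
}

# random repeat intervals within [0, len)
random_intervals <- function(len, n, max_w = 40) {
  st <- sample.int(len - max_w, n, replace = TRUE) - 1L
  data.frame(chrom = "chr1", start = st,
             end = st + sample.int(max_w, n, replace = TRUE))
}

# a small GC-annotated window set over a fully accessible genome, for tests
# that only need aligned counts/windows
toy_windows <- function(n, gc = NULL, span = 1000L) {
  m <- accessibility_mask(
    c(chr1 = n * span),
    list(chr1 = data.frame(start = 0L, end = n * span)))
  w <- partition_accessible(m, span)
  w$gc <- if (is.null(gc)) runif(n) else gc
  w
}

toy_track <- function(counts, windows, state = "raw", sample = "s") {
  count_track(counts, windows$index,
              library_size = sum(counts) + 1, state = state, sample = sample)
}
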