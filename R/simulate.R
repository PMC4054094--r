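#' Simulation configuration
#'
#' Parameters of the DNA-isolation retrieval-bias simulator. The model is
#' window-level: a library sequenced from tissue t after a lysis duration of
#' `tau` minutes samples reads multinomially over windows with weight
#'
#' \deqn{w_i = c_i \cdot f_{GC}(g_i) \cdot e^{-\beta(\tau) H_{t,i}},
#'   \qquad \beta(\tau) = \beta_0 e^{-\tau/\tau_0}}
#'
#' where `c_i` is the germline copy factor of window i for the strain
#' sequenced, `g_i` its GC fraction, `H_{t,i}` in `[0, 1]` the chromatin
#' compaction of window i in tissue t, and `f_GC` a unimodal library-prep
#' GC-efficiency curve. Long lysis (`tau >> tau_0`) releases protein-bound
#' DNA, so the chromatin term decays toward equimolar retrieval while the GC
#' term persists.
#'
#' @param chrom_lengths Named chromosome lengths (bp).
#' @param isochore_scale GC autocorrelation length (bp) of the simulated
#'   isochore structure.
#' @param gc_range Range the window-scale GC target track is clipped to.
#' @param repeat_density Fraction of each chromosome covered by simulated
#'   repeat annotation.
#' @param n_gaps,gap_length Number and length (bp) of assembly gaps (N-runs)
#'   per chromosome.
#' @param tissues Tissue names; one compaction track is simulated per tissue.
#' @param tissue_divergence Scale of the independent per-tissue component of
#'   compaction (0 = all tissues identical).
#' @param gc_coupling Weight in `[0, 1]` tying compaction to `1 - GC`
#'   (heterochromatin is AT-rich at isochore scale).
#' @param compaction_scale Autocorrelation length, in windows, of the
#'   compaction fields.
#' @param gc_bias List `peak`, `slope`, `floor`, `flat` defining
#'   `f_GC(g) = max(floor, 1 - slope (g - peak)^2)`, or a flat curve.
#' @param beta0 Maximal chromatin bias strength (at `tau = 0`).
#' @param tau0 Lysis decay constant (minutes).
#' @param lysis_times Lysis durations (minutes); overnight is encoded as
#'   1440.
#' @param cnv_list `NULL` or data.frame `chrom`, `start`, `end`,
#'   `copy_factor`, `strain`: germline CNVs per strain.
#' @param strains Strain names; strains without entries in `cnv_list` have
#'   copy factor 1 everywhere.
#' @param n_reads Reads per simulated library.
#' @param window_size Accessible bp per analysis window.
#' @param seed Base seed; all randomness derives from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(chrom_lengths = c(chr1 = 8e6, chr2 = 4e6),
                       isochore_scale = 1e6,
                       gc_range = c(0.30, 0.60),
                       repeat_density = 0.30,
                       n_gaps = 2L, gap_length = 5e4,
                       tissues = c("brain", "liver"),
                       tissue_divergence = 0.6,
                       gc_coupling = 0.5,
                       compaction_scale = 25,
                       gc_bias = list(peak = 0.45, slope = 3, floor = 0.3,
                                      flat = FALSE),
                       beta0 = 1.2, tau0 = 60,
                       lysis_times = c(10, 30, 60, 120, 1440),
                       cnv_list = NULL,
                       strains = "ref",
                       n_reads = 1e6,
                       window_size = 20000L,
                       seed = 1L) {
  stopifnot(all(chrom_lengths > 0), !is.null(names(chrom_lengths)),
            gc_range[1] >= 0, gc_range[2] <= 1, gc_range[1] <= gc_range[2],
            repeat_density >= 0, repeat_density < 1,
            tissue_divergence >= 0, beta0 >= 0, tau0 > 0)
  if (!is.null(cnv_list)) {
    stopifnot(all(c("chrom", "start", "end", "copy_factor", "strain")
                  %in% names(cnv_list)), all(cnv_list$copy_factor > 0))
  }
  structure(as.list(environment()), class = "sim_config")
}

# chromatin bias strength after tau minutes of lysis
beta_tau <- function(config, tau) {
  if (any(tau < 0)) abort("lysis time must be >= 0")
  config$beta0 * exp(-tau / config$tau0)
}

# library-prep GC efficiency curve
f_gc <- function(config, gc) {
  b <- config$gc_bias
  if (isTRUE(b$flat)) return(rep(1, length(gc)))
  pmax(b$floor, 1 - b$slope * (gc - b$peak)^2)
}

# stationary AR(1) noise, standardized, autocorrelation length `scale` steps
ar1_field <- function(n, scale) {
  phi <- exp(-1 / scale)
  x <- numeric(n)
  x[1] <- rnorm(1)
  innov <- rnorm(n - 1L, sd = sqrt(1 - phi^2))
  for (t in seq_len(n - 1L)) x[t + 1L] <- phi * x[t] + innov[t]
  x
}

#' Simulate an isochore-structured genome with repeats and gaps
#'
#' The per-position GC probability follows a mean-reverting random walk
#' (AR(1) at 1 kb resolution) with autocorrelation length
#' `isochore_scale`, clipped to `gc_range`; bases are drawn independently at
#' that probability. Repeat annotation intervals are placed at random to a
#' total density of `repeat_density`, and `n_gaps` N-runs of `gap_length` bp
#' are inserted per chromosome.
#'
#' @param config A [sim_config()].
#' @param seed Seed (defaults to `config$seed`).
#' @return List with `genome` ([Biostrings::DNAStringSet]), `repeats`
#'   (data.table `chrom`, `start`, `end`) and `gc_target` (data.table of the
#'   1 kb GC probability track).
#' @export
simulate_genome <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  local_seed(seed, {
    res <- 1000L
    seqs <- list(); rpts <- list(); gctr <- list()
    for (chrom in names(config$chrom_lengths)) {
      len <- as.integer(config$chrom_lengths[[chrom]])
      nbin <- ceiling(len / res)
      mu <- mean(config$gc_range)
      sd_st <- diff(config$gc_range) / 4
      g <- mu + sd_st * ar1_field(nbin, config$isochore_scale / res)
      g <- pmin(pmax(g, config$gc_range[1]), config$gc_range[2])
      p <- rep(g, each = res)[seq_len(len)]
      strong <- runif(len) < p
      pur <- runif(len) < 0.5
      base <- ifelse(strong, ifelse(pur, "G", "C"), ifelse(pur, "A", "T"))
      # assembly gaps
      gaps <- data.table::data.table(start = integer(0), end = integer(0))
      if (config$n_gaps > 0 && config$gap_length > 0) {
        gs <- sort(sample.int(len - as.integer(config$gap_length),
                              config$n_gaps))
        gaps <- merge_intervals0(gs, gs + as.integer(config$gap_length))
        for (j in seq_len(nrow(gaps))) {
          base[(gaps$start[j] + 1L):gaps$end[j]] <- "N"
        }
      }
      seqs[[chrom]] <- paste(base, collapse = "")
      # repeat annotation: exponential-ish length mixture, uniform placement
      target <- config$repeat_density * len
      if (target > 0) {
        n_est <- ceiling(target / 1200) * 2L
        rl <- pmax(200L, as.integer(stats::rexp(n_est, rate = 1 / 1000)))
        rs <- sample.int(len, n_est, replace = TRUE) - 1L
        re <- pmin(rs + rl, len)
        cum_ok <- cumsum(as.numeric(re - rs)) <= target
        keep <- which(cum_ok | seq_along(rs) == 1L)
        riv <- merge_intervals0(rs[keep], re[keep])
        rpts[[chrom]] <- data.table::data.table(chrom = chrom,
                                                start = riv$start,
                                                end = riv$end)
      }
      gctr[[chrom]] <- data.table::data.table(
        chrom = chrom, start = (seq_len(nbin) - 1L) * res,
        end = pmin(seq_len(nbin) * res, len), gc = g)
    }
    genome <- Biostrings::DNAStringSet(unlist(seqs))
    reps <- if (length(rpts)) data.table::rbindlist(rpts) else
      data.table::data.table(chrom = character(0), start = integer(0),
                             end = integer(0))
    list(genome = genome, repeats = reps,
         gc_target = data.table::rbindlist(gctr))
  })
}

#' Simulate per-tissue chromatin-compaction tracks
#'
#' Compaction `H` in `[0, 1]` per window and tissue: a logistic squash of a
#' shared smooth field (AR(1) over window index), optionally coupled to
#' `1 - GC` with weight `gc_coupling`, plus an independent per-tissue smooth
#' perturbation scaled by `tissue_divergence`. High `H` stands for densely
#' packed heterochromatin whose DNA resists retrieval under short lysis.
#'
#' @param config A [sim_config()].
#' @param windows A GC-annotated [window_set].
#' @param seed Seed (defaults to `config$seed + 1`).
#' @return Numeric matrix, one column per tissue, rows matching `windows`.
#' @export
simulate_compaction <- function(config, windows, seed = config$seed + 1L) {
  stopifnot(inherits(config, "sim_config"), inherits(windows, "window_set"))
  n <- nrow(windows)
  local_seed(seed, {
    shared <- ar1_field(n, config$compaction_scale)
    gcz <- windows$gc
    gcz[is.na(gcz)] <- mean(gcz, na.rm = TRUE)
    gcz <- as.numeric(scale(1 - gcz))
    base <- (1 - config$gc_coupling) * shared + config$gc_coupling * gcz
    H <- vapply(config$tissues, function(t) {
      pert <- ar1_field(n, config$compaction_scale)
      stats::plogis(base + config$tissue_divergence * pert)
    }, numeric(n))
    colnames(H) <- config$tissues
    H
  })
}

# germline copy factor per window for one strain (overlap-weighted)
window_copy_factor <- function(windows, cnv_list, strain) {
  cf <- rep(1, nrow(windows))
  if (is.null(cnv_list)) return(cf)
  cnv <- cnv_list[cnv_list$strain == strain, , drop = FALSE]
  for (j in seq_len(nrow(cnv))) {
    rows <- which(windows$chrom == cnv$chrom[j])
    if (!length(rows)) next
    ovl <- pmax(0, pmin(windows$end[rows], cnv$end[j]) -
                   pmax(windows$start[rows], cnv$start[j]))
    frac <- ovl / (windows$end[rows] - windows$start[rows])
    cf[rows] <- cf[rows] * (1 + frac * (cnv$copy_factor[j] - 1))
  }
  cf
}

#' Simulate a sequencing library under the retrieval-bias model
#'
#' Draws `n_reads` read start positions: windows are sampled multinomially
#' with weight `copy_factor * f_GC(gc) * exp(-beta(tau) * H)`, then positions
#' are placed uniformly over each window's accessible bases.
#'
#' @param windows A GC-annotated [window_set] (carries its mask).
#' @param compaction Numeric vector: the tissue's compaction per window.
#' @param tau Lysis duration (minutes).
#' @param config A [sim_config()].
#' @param strain Strain name (selects CNVs from `config$cnv_list`).
#' @param n_reads Library size (defaults to `config$n_reads`).
#' @param seed Seed (required).
#' @return List with `reads` (a [read_set()]) and `truth` (data.table of
#'   per-window `gc`, `compaction`, `copy_factor`, `retrieval_bias` — the
#'   unnormalized weight — and `expected_share`, `expected_count`).
#' @export
simulate_reads <- function(windows, compaction, tau, config,
                           strain = "ref", n_reads = config$n_reads, seed) {
  stopifnot(inherits(windows, "window_set"),
            length(compaction) == nrow(windows))
  if (tau < 0) abort("lysis time tau must be >= 0")
  gc <- windows$gc
  fgc <- f_gc(config, ifelse(is.na(gc), mean(gc, na.rm = TRUE), gc))
  cf <- window_copy_factor(windows, config$cnv_list, strain)
  w <- cf * fgc * exp(-beta_tau(config, tau) * compaction)
  share <- w / sum(w)
  truth <- data.table::data.table(
    window = windows$index, chrom = windows$chrom,
    start = windows$start, end = windows$end,
    gc = gc, compaction = compaction, copy_factor = cf,
    retrieval_bias = w, expected_share = share,
    expected_count = share * n_reads)
  counts <- local_seed(seed, as.integer(rmultinom(1L, n_reads, share)))
  pos <- local_seed(seed + 1L, place_reads(windows, counts))
  list(reads = read_set(pos$chrom, pos$pos), truth = truth,
       tau = tau, strain = strain)
}

# uniform positions over each window's accessible bases
place_reads <- function(windows, counts) {
  mask <- attr(windows, "mask")
  chunks_chrom <- list(); chunks_pos <- list()
  for (ch in unique(windows$chrom)) {
    rows <- which(windows$chrom == ch)
    iv <- mask$accessible[[ch]]
    win <- ir0(windows$start[rows], windows$end[rows])
    acc <- ir0(iv$start, iv$end)
    hits <- IRanges::findOverlaps(win, acc)
    pieces <- IRanges::pintersect(win[S4Vectors::queryHits(hits)],
                                  acc[S4Vectors::subjectHits(hits)])
    q <- S4Vectors::queryHits(hits)
    pstart <- BiocGenerics::start(pieces) - 1L
    pwidth <- IRanges::width(pieces)
    pos_list <- vector("list", length(rows))
    for (r in seq_along(rows)) {
      cnt <- counts[rows[r]]
      if (cnt == 0L) next
      pw <- pwidth[q == r]; ps <- pstart[q == r]
      if (!length(pw)) next
      cum <- cumsum(pw)
      off <- sample.int(cum[length(cum)], cnt, replace = TRUE) - 1L
      piece <- findInterval(off, cum) + 1L
      pos_list[[r]] <- ps[piece] + (off - c(0L, cum)[piece])
    }
    chrompos <- unlist(pos_list)
    chunks_chrom[[ch]] <- rep(ch, length(chrompos))
    chunks_pos[[ch]] <- chrompos
  }
  list(chrom = unlist(chunks_chrom, use.names = FALSE),
       pos = unlist(chunks_pos, use.names = FALSE))
}
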