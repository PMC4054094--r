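---
title: "Methods: coverage-bias analysis and retrieval-bias simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coverage-bias analysis and retrieval-bias simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, parameter choices and numerical
conventions behind `covbias`, in the spirit of a methods section: what each
stage computes, which decisions were genuinely open, and what the synthetic
validation does and does not establish about real data.

## The bias model

Per-region DNA quantification is never perfectly equimolar. `covbias` works
at the scale of genomic windows and decomposes the expected read count of
window *i* in a library from tissue *t* as

$$
E[N_i] \;\propto\; c_i \cdot f_{GC}(g_i) \cdot e^{-\beta(\tau)\,H_{t,i}},
$$

with three multiplicative terms:

* `c_i` — the true copy factor (1 outside CNVs), the only term a copy
  number analysis wants to see;
* `f_GC(g_i)` — a GC-dependent library-preparation/hybridization
  efficiency, identical across tissues of one individual;
* `exp(−β(τ)·H_{t,i})` — differential DNA retrieval during isolation:
  `H_{t,i} ∈ [0, 1]` is the chromatin compaction of window *i* in tissue
  *t*, and `β(τ) ≥ 0` the strength of the retrieval penalty after a lysis
  of duration τ. Because `H` is tissue-specific, this term — unlike GC
  bias — survives any within-library correction and masquerades as
  tissue-specific copy number.

The analysis half of the package makes no parametric assumption about
`f_GC`: the nearest-GC-neighbor median correction removes *any*
GC-dependent trend. The simulator half instantiates all three terms
explicitly so that each claim about the analysis can be tested against
ground truth.

## Windowing

Windows contain a fixed amount of *accessible* sequence — positions outside
annotated repeats and assembly gaps (maximal `N` runs) — rather than a fixed
genomic span, so that expected counts are comparable across windows
(default `W` = 20 000 accessible bp). A second mode accumulates non-gap
sequence only (repeats stay in; default `S` = 100 000 bp), appropriate for
longer-insert libraries where repeat placement is less problematic.

Conventions the window grammar fixes explicitly:

* **Coordinates** are 0-based half-open everywhere, BED dialect on disk.
* **Accumulation rule**: scanning accessible intervals left to right, a
  boundary is cut exactly when the accumulated accessible count reaches
  `W`; every window except possibly the last per chromosome holds exactly
  `W` accessible bp.
* **Spans abut**: each window starts where the previous one ended, so any
  read between the first and last accessible base is attributable to
  exactly one window. Reads in leading/trailing unwindowed sequence are
  discarded and counted in the run log.
* **Terminal remainders** are kept iff they hold at least `W/2` accessible
  bp. A tiny terminal window would have inflated count variance; always
  keeping or always dropping are both defensible, the half-rule bounds the
  distortion either way. Dropped bp are reported.
* Windows never straddle chromosomes; GC is `(#G+#C)/(#A+#C+#G+#T)` over a
  window's accessible bases, ambiguity codes excluded from the denominator;
  windows with no unambiguous accessible base carry `NA` GC and are
  excluded from GC correction.

Both partition modes are validated exactly against a per-base scanning
brute force on random genomes up to 100 kb, including conservation of total
accessible bp.

## Counting and depth normalization

A read belongs to the window whose span contains its *start position* — the
simplest deterministic rule for single-position depth-of-coverage data;
midpoint or fractional-overlap assignment would require fragment lengths
the input (BED3 / chrom-pos tables) does not reliably carry.
Duplicate-flagged reads are excluded from counts and library sizes.

Three depth normalizations are provided because they answer different
questions: reads-per-million for cross-library ratio tracks; random
downsampling (uniform without replacement, seeded) when libraries should be
made *statistically* equivalent, not just rescaled; and cross-sample
quantile normalization when only the shape of the evenness distribution is
of interest. Quantile normalization uses the standard rank/mean
construction; tied windows receive the mean of the reference values over
their rank range, which keeps the map monotone and deterministic. A
consequence worth knowing: with ties, the output multisets of different
tracks are no longer exactly identical (tie groups collapse several
reference values into one mean); sums are still preserved exactly, and on
tie-free data the classical identical-sorted-values property holds and is
verified against `limma::normalizeQuantiles`.

Every stochastic operation takes an explicit `seed` and runs under a
locally scoped Mersenne-Twister; nothing touches the caller's RNG state.

## GC correction

Window *i* is corrected as `N_corr = N_med · N_obs / N_medGC`, where
`N_medGC` is the median count over the `k = 100` windows most similar in GC
content. Open details fixed here:

* The window itself is **included** in its own neighborhood: the all-equal
  case then collapses to the exact identity, and edge windows are not
  treated asymmetrically.
* Ties in GC distance are broken by genomic proximity (`|j − i|`), then by
  index — the correction is bit-reproducible.
* The median of an even-length set is the mean of the two central values.
* A zero neighborhood median cannot rescale a window: such windows become
  `NA`, are flagged, and are excluded from downstream ratios — never
  infinity.
* `k` larger than the usable window count is clamped with a warning;
  an all-zero track is an error.
* Correction is applied per library; neighborhoods are never pooled across
  libraries, since each library has its own GC response.

The implementation finds neighborhoods with a two-sided frontier walk in
GC-sorted order (O(n·k) plus tie resolution) and is tested bit-exactly
against a brute-force oracle that sorts all windows per target, including
forced-tie and zero-median instances. Properties verified on synthetic
counts: the corrected-to-GC correlation of Poisson counts with a quadratic
GC effect in [0.5, 2] falls below |r| = 0.05 at 5 000 windows with the CV
reduced by well over half; correction is equivariant under count rescaling;
and the median of corrected counts stays within 5% of `N_med`.

## Evenness, dispersion, smoothing

Evenness histograms bin reads-per-window at a configurable width (default
10 reads — the bin width used for display curves is not critical and is
exposed as a parameter). Dispersion summaries (sd, IQR, unscaled MAD,
CV = sd/mean) use R's type-7 linear-interpolation quantiles so values are
bit-reproducible across platforms. Display smoothing reduces
*non-overlapping* blocks of `k` consecutive values to their median (one
point per block, matching the dot-per-block density of conventional aCGH
plots; a sliding median would change the visual bandwidth), with the same
`≥ k/2` terminal-block rule as windowing, and blocks never straddle
chromosomes.

## Differential segmentation

Ratios are `L_i = log2((a_i + 0.5)/(b_i + 0.5))`; the 0.5 pseudocount keeps
low-count windows finite and approximately unbiases the log under Poisson
noise. A window is deviant-up when `2^L ≥ 1 + threshold`, deviant-down when
`2^L ≤ 1 − threshold` (default threshold 0.10). Maximal same-direction runs
of deviant windows are merged across at most `max_gap = 1` interleaved
non-deviant windows (an opposite-direction deviant window always splits a
run), runs with at least `min_windows = 3` deviant windows become segments,
and segment boundaries snap to the first/last deviant window so the
reported extent — totaled as `total_affected_mb` — is conservative.
`min_windows` and `max_gap` are explicit package choices: small enough to
catch a 10-window event, strict enough that alternating noise cannot chain.

One degeneracy deserves a warning. The segmenter classifies windows against
a hard threshold, so an effect whose true magnitude equals the threshold
exactly (a 1.10 copy factor tested at threshold 0.10) puts every in-region
window *on* the decision boundary: each is deviant with probability ~0.5
regardless of sequencing depth, the run structure fragments, and recovery
metrics (Jaccard overlap, affected Mb) collapse. This is a property of any
hard-threshold rule, not of the implementation; reliable recovery needs the
true effect strictly inside the detectable region (the `two-strain-cnv`
preset plants 1.25 and 0.75 factors, recovered with Jaccard ≈ 0.9–1.0), and
effects *at* the threshold should be interpreted as the boundary class they
are. The test suite keeps one check at the exact-boundary configuration to
document this behaviour.

## Feature correlations

Interval annotations become per-window coverage fractions of the genomic
span; step signals become span-length-weighted means (windows without
signal are `NA`; missing data are handled by pairwise-complete deletion per
feature). Pearson r is computed with a two-sided p from the t-distribution
with n − 2 df. These p-values are **nominal**: adjacent windows are
strongly autocorrelated, so the effective sample size is far below the
window count and the p-values overstate significance. They are reported for
orientation, not inference, and no autocorrelation correction is attempted.

## The simulator and its scope

`simulate_genome` draws a per-position GC probability from a mean-reverting
AR(1) walk at 1 kb resolution (autocorrelation length `isochore_scale`,
default 1 Mb — isochore scale), clipped to `gc_range` (default 0.30–0.60,
the mammalian window-scale range), then samples bases independently;
repeats are placed to a target density (default 0.30) with ~1 kb
exponential lengths, and `N` gaps inserted. `simulate_compaction` builds
`H` per tissue as a logistic squash of a shared smooth field, optionally
coupled to `1 − GC` (weight `gc_coupling`, default 0.5 — heterochromatin is
AT-rich at isochore scale), plus an independent smooth per-tissue
perturbation scaled by `tissue_divergence` (default 0.6, giving
inter-tissue compaction correlations around 0.7 — similar tissues, visible
differences). `simulate_reads` draws window counts multinomially from the
bias weights and places read starts uniformly within each window's
accessible bases.

Two simulator-specific choices to be aware of:

* **β(τ) is exponential decay**, `β(τ) = β₀ e^{−τ/τ₀}` (defaults β₀ = 1.2,
  τ₀ = 60 min; overnight encoded as τ = 1440 min). The empirical
  observation this reflects is monotone improvement of evenness with lysis
  duration; the functional form is the simplest monotone one-constant
  choice, is config-overridable, and no conclusion in the package depends
  on its exact shape — only on monotonicity.
* **`f_GC` defaults to a unimodal quadratic** peaking at GC 0.45 with floor
  0.3, mimicking standard library-prep GC curves; a flat curve is available
  for controls.

The model is deliberately **window-level**: fragment-level GC
thermodynamics, sequencing error, quality scores, mate-pair inserts and
alignment artifacts are all out of scope. Consequently, passing recovery
tests shows that the *analysis machinery* is correct under the stated
generative model — it does not show that real tissues follow that model,
that real compaction tracks are logistic-AR fields, or that real β(τ)
is exponential. What the synthetic studies *do* establish: GC correction
removes exactly the GC term and provably cannot remove the tissue term;
dispersion and tissue-difference widths are monotone in β(τ); planted
copy factors strictly inside the threshold are segmented correctly; and
the regression of log expected-normalized count on `H` recovers −β within
10% at 5 000 windows — the bias is identifiable at desk scale.

## Problem sizes and reproducibility

The shipped test suite and acceptance script run on genomes of 2–12 Mb
(≈ 80–440 windows of 20 kb accessible sequence) with 0.2–1 M reads per
library — sizes chosen so every stage, including 10-library lysis series,
completes in seconds to a couple of minutes while keeping per-window depths
(≈ 300–2 400 reads) high enough that the tested effects dominate sampling
noise. Fixture presets are fully deterministic: identical preset + seed
give byte-identical file trees (verified by manifest MD5s), and the
pipeline caches stage outputs on input/parameter hashes, so reruns reuse
results and a changed seed recomputes only downstream stages.

## Known limitations

* Binary accessibility masking only; no mappability scores.
* The counting rule ignores fragment length (start-position assignment).
* Segmentation has no significance model — it quantifies thresholded
  contiguity, not statistical evidence; segments at the threshold boundary
  are unstable by construction (above).
* Correlation p-values are nominal (autocorrelation, above).
* The simulator does not emit FASTQ, model sequencing error, or simulate
  alignment; it produces aligned read positions directly.
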