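# covbias

Depth-of-coverage bias analysis for low-pass whole-genome sequencing and
aCGH-style data, paired with a simulator of DNA-isolation retrieval bias.

## The problem

Genome-wide DNA quantification — read depth in sequencing, log2 ratios on
tiling arrays — shows megabase-scale "wave" patterns that do not reflect true
copy number. Part of the wave tracks GC content, but a second component is
tissue-specific: densely packed heterochromatin releases its DNA less
readily during isolation, so euchromatic regions are over-represented
relative to heterochromatic ones, and the imbalance depends on how
stringently the sample was lysed (e.g. the duration of proteinase K
treatment). Because the artifact mimics somatic copy number differences
between tissues, it matters for anyone calling CNVs from read depth.

`covbias` provides the analysis machinery to quantify this bias and the
simulation machinery to study it under known ground truth:

* **Windowing** — partition a genome into windows containing a fixed amount
  of NGS-accessible sequence (non-repeat, non-gap; default W = 20 kb), or a
  fixed non-gap span (default S = 100 kb). Windows abut; each carries its
  accessible-base count and GC fraction.
* **Counting & normalization** — per-window read counts (duplicates
  excluded), reads-per-million scaling, random downsampling to a common
  depth, and cross-sample quantile normalization.
* **GC correction** — each window is rescaled against the median count of
  the k = 100 windows with most similar GC content:
  `N_corr = N_med · N_obs / N_medGC`,
  where `N_med` is the library's median window count and `N_medGC` the
  median over the GC neighborhood. This removes any GC-dependent trend while
  leaving GC-independent (e.g. chromatin-driven) structure in place.
* **Evenness metrics** — histograms of reads-per-window, dispersion
  summaries (sd, IQR, unscaled MAD, CV), tissue-difference distributions,
  and blockwise median smoothing for display.
* **Differential segmentation** — per-window log2 ratios between two
  depth-matched samples, and a threshold-run segmenter reporting contiguous
  regions whose apparent copy number differs by at least a given fraction
  (default 10%), totaled in megabases.
* **Feature correlation** — bin interval annotations (SINE density, gene
  density) and step signals (replication timing) onto the window grid and
  compute a Pearson correlation panel against any coverage or ratio track.
* **Simulator** — an isochore-structured genome with repeats and gaps,
  per-tissue chromatin-compaction tracks, and read libraries drawn with
  per-window weight `copy_factor · f_GC(gc) · exp(−β(τ)·H)`, where `H` is
  compaction and `β(τ) = β₀·e^(−τ/τ₀)` decays with lysis duration τ. Presets
  (`tiny`, `gc-only`, `chromatin-only`, `lysis-series`, `two-strain-cnv`)
  encode ready-made study scenarios with truth tables.

## Worked example

```r
library(covbias)

cfg   <- preset_config("tiny")          # 2.3 Mb genome, 2 tissues, 2 lysis times
study <- simulate_study(cfg)
study$windows
#> window_set: 84 windows, mode=accessible-content, size=20000 bp
#>    chrom start   end accessible_bp     gc index
#> 1:  chr1     0 25815         20000 0.4298     0
#> 2:  chr1 25815 58178         20000 0.4176     1
#> ...

brain <- count_reads(study$windows, study$libraries[["ref_brain_tau30"]]$reads, "brain")
liver <- count_reads(study$windows, study$libraries[["ref_liver_tau30"]]$reads, "liver")

dispersion(brain)                        # 30 min lysis: wide evenness curve
#> dispersion over 84 windows: sd=204.936 iqr=315.750 mad=158.000 cv=0.0861
dispersion(count_reads(study$windows, study$libraries[["ref_brain_tau1440"]]$reads))
#> dispersion over 84 windows: sd=56.238 iqr=69.750 mad=36.000 cv=0.0236
```

Overnight lysis (τ = 1440 min) cuts the genome-wide spread of
reads-per-window almost four-fold: the chromatin term of the retrieval bias
has decayed, only GC bias and Poisson noise remain. Tissue comparison after
GC correction still finds apparent copy number differences, because the
chromatin bias differs between tissues and GC correction cannot see it:

```r
ratio <- log2_ratio(gc_correct(brain, study$windows, k = 20),
                    gc_correct(liver, study$windows, k = 20))
segment_differential(ratio, study$windows, threshold = 0.10)
#>    chrom   start     end n_windows mean_ratio direction
#> 1:  chr1   82361  584637        18      0.271      gain
#> 2:  chr1 1323344 1500000         7      0.267      gain
#> 3:  chr2  430886  596456         6     -0.247      loss
#> affected Mb: 0.845
```

At 30 min of lysis, 0.85 Mb of this 2.3 Mb genome shows apparent
tissue-specific copy number differences of at least 10% — none of them real
(the tissues share one genome; the simulator's truth tables confirm the
regions are high-compaction-contrast, not CNV).

A thin command-line wrapper covering the same steps ships in
`inst/cli/covbias.R` (verbs: `windows`, `count`, `downsample`, `gccorrect`,
`evenness`, `compare`, `correlate`, `simulate`, `run`); `run` drives the
whole pipeline from a YAML configuration with per-stage caching and a run
log.

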