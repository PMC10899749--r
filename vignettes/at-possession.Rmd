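---
title: "Quantifying possession of AT-rich DNA from ChIP-seq peak composition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying possession of AT-rich DNA from ChIP-seq peak composition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(atpossess)
```

## The scientific question

Xenogeneic silencers such as H-NS repress horizontally acquired genes by
occupying AT-rich DNA: their robust, near-exclusive hold on such regions is
what we call *possession* of AT-rich DNA. Post-translational modification of
the DNA-binding domain — here modelled after acetylation of a key lysine —
can weaken that hold. `atpossess` quantifies possession from the sequence
composition of ChIP-seq peak calls:

1. **Summit-window AT content.** Each peak contributes the AT fraction of the
   window 49 bp either side of its summit (99 bp); a peak set is summarised
   by the mean window AT% against the genome-wide and genomic-island AT%.
2. **Oligonucleotide usage deviation.** Per peak, overlapping dinucleotide
   and trinucleotide frequencies (16 and 64 categories) divided by the
   uniform expectation (1/16 = 0.0625, 1/64 = 0.015625). For each k-mer, the
   Spearman correlation between usage deviation and recruitment (ChIP fold
   enrichment) across peaks identifies which words recruit the protein.
3. **Binned AT-recruitment curve.** Recruitment is divided into 20 equal
   ranges; an OLS fit of bin-mean AT% on bin-mean recruitment yields a slope
   in AT% per fold-enrichment unit. A *steeper* slope means the protein
   needs a larger AT excess per unit of occupancy — i.e. weaker possession.
4. **TSS metaprofile.** A deepTools-computeMatrix analogue over bedGraph
   coverage and BED6 TSS records shows whether binding concentrates at
   transcription start sites.
5. **ΔΔCt quantification** for ChIP-qPCR enrichment (normalized to a
   nonspecific `dnaA` locus) and qRT-PCR relative expression.

## The simulator and what it emulates

Real ChIP-seq validation would need raw reads, alignment and peak calling,
which are out of scope here; instead a generative model with recorded ground
truth drives all end-to-end tests. `sim_config()` encodes the study
conditions:

* **Genome**: one 500 kb contig, i.i.d. bases at background AT 0.403 (the
  genome-wide average of the modelled fish pathogen), with 20 non-overlapping
  5 kb islands redrawn at AT 0.55. The island AT is set well above the
  background so that island-borne sites span the AT range actually observed
  in silencer peaks (50–60%+), not the mild genome-average elevation of
  annotated islands.
* **Sites and recruitment**: `n_sites = 300` candidate summits. With
  probability `tss_bias_p0 * (1 - alpha)` a summit lands within ±50 bp of a
  TSS, else uniformly. Recruitment is linear-with-threshold in the
  summit-window AT fraction `a`:
  `r = beta * (1 - alpha) * max(0, a - a0) + r0 * (1 + kappa * alpha) + noise`,
  and sites with `r >= call_threshold` become peaks. The linear form was
  chosen over a sigmoid because it gives the binned AT-vs-recruitment slope
  the closed form `s_true = 1 / (beta * (1 - alpha))`, making parameter
  recovery exact in the noiseless limit.
* **Acetylation** enters twice, mirroring the biology: it attenuates the
  specific term (factor `1 - alpha`) and inflates nonspecific binding
  (`kappa > 0`), reproducing the observed combination of lower peak AT%,
  fewer TSS-proximal events, abundant low-fold non-TSS peaks, and a steeper
  AT-recruitment slope in the acetyl-mimic.
* **Defaults**: `beta_spec = 200` places native slopes near 0.5 AT% per fold
  and alpha = 0.8 slopes near 2.5, with fold enrichments spanning ~3–30;
  `r_nonspecific = 1.5` matches the low (~1.5-fold) recruitment of diffuse
  nonspecific peaks; `call_threshold = 3` sits above the nonspecific
  baseline for every alpha < 1 so that, at low noise, called peaks obey the
  linear law exactly; `noise_sd = 0.5` keeps the directional contrasts
  realistic rather than trivial. `tss_island_frac = 0.6` places most TSS in
  islands, reflecting that silenced promoters sit in AT-rich acquired loci —
  without it, TSS-targeted sites would rarely clear the calling threshold
  and the metaprofile would be uninformative.
* **Ct tables**: `ct = base - log2(fold) + noise`, reference target fixed at
  fold 1, so the ΔΔCt calculators must return the programmed folds exactly
  when noise is zero.

What the generator does **not** emulate: read-level noise, fragment-size
effects, replicate structure, mappability, motifs (islands are compositional,
not motif-bearing), and GC-dependent coverage bias. Passing tests therefore
demonstrate that the *analysis* is correct and directionally faithful, not
that it would reproduce any particular organism's numbers.

## Numerical and design choices

* **Coordinates** are 0-based half-open everywhere internally, matching
  BED/narrowPeak/bedGraph on disk.
* **Recruitment column**: the narrowPeak `signalValue` (column 7) is read as
  the recruitment level — fold enrichment is its conventional content; this
  is an assumption, as peak callers also emit p/q scores.
* **Summit fallback**: a narrowPeak summit of −1 falls back to the interval
  midpoint so no peak is dropped.
* **Window length**: summit ±49 bp (99 bp). A 100 bp window cannot be
  summit-symmetric; the halfwidth is a parameter for users who prefer other
  conventions.
* **Truncated windows** (clipped at contig ends) are excluded from set-level
  statistics rather than padded — padding would bias AT% near contig
  boundaries; exclusions are reported.
* **N policy**: ambiguity codes collapse to `N` on input; `N` bases are
  excluded from AT numerator and denominator, and k-mer windows containing
  `N` are skipped.
* **Per-peak vs pooled averaging**: the set-level AT% defaults to the mean
  of per-peak fractions (`pooling = "per_peak"`); pooling all bases before
  the ratio is available since published summaries rarely state which was
  used.
* **"Successive" k-mers** are overlapping step-1 windows (`L - k + 1` per
  sequence); non-overlapping parsing would leave most of the 16/64
  categories empty in 99 bp windows.
* **Spearman p-values** use the t approximation (`n - 2` df) for `n > 10`
  and a seeded 10,000-draw permutation otherwise; both modes can be forced.
  BH-adjusted q-values accompany raw p-values across the 4^k tests of each
  k. Note rho is identical on raw frequencies and on deviations (positive
  scaling), so the deviation convention affects presentation only.
* **Binning**: equal-width recruitment ranges by default ("ranges" of the
  fold-enrichment axis); quantile binning is an option. Empty bins are
  dropped from the fit, never interpolated. Because slopes above 1 cannot be
  correlation coefficients, the OLS slope of bin means is the headline
  statistic, with bin-index slope and Pearson r reported alongside.
* **Overlap criterion** for differential peak comparison is ≥1 bp by
  default, with a configurable minimum-overlap fraction of the shorter peak.
* **TSS matrix defaults** (500/500/10 bp) are sized for dense bacterial
  genomes; off-contig bins are missing values, excluded from column means,
  to avoid edge artifacts.
* **ΔΔCt** uses replicate means before differencing and the pure `2^-ΔΔCt`
  form without amplification-efficiency correction; per-replicate ratios are
  emitted for dispersion.

## Problem sizes and verification

The test suite regenerates all data in code: unit tests run the simulator at
100 kb / 150 sites, while end-to-end checks use the default 500 kb / 300
sites and, for parameter recovery, 500 sites at `noise_sd = 0.02`, where the
binned slope matches `s_true` within 10% (typically within 0.1%). The
directional signature — mean called-peak AT% non-increasing and slope
non-decreasing across alpha ∈ {0, 0.4, 0.8} — is checked over ten seeds.
Independent oracles (character-by-character k-mer enumeration, rank-then-
Pearson Spearman, quadratic-time overlap scans, per-base coverage averages)
back every nontrivial computation.

## Worked example

```{r example, eval = FALSE}
cfg0 <- sim_config(seed = 1, alpha_acetyl = 0)    # native silencer
cfg8 <- sim_config(seed = 1, alpha_acetyl = 0.8)  # acetylation mimic
g    <- simulate_genome(cfg0)
tss  <- simulate_tss(cfg0, g)
nat  <- simulate_peaks(cfg0, g, tss)
ace  <- simulate_peaks(cfg8, g, tss)

peakset_at_summary(nat$peaks, g, attr(g, "islands"))
peakset_at_summary(ace$peaks, g, attr(g, "islands"))
bin_at_vs_recruitment(nat$peaks, g)
bin_at_vs_recruitment(ace$peaks, g)
subset(correlate_usage_recruitment(nat$peaks, g, k = 2),
       kmer %in% c("AT", "TA", "CG", "GC"))
```

## Known limitations

* Single-contig simulation; multi-contig genomes are supported by the
  analysis functions but not generated.
* The coverage model (floor plus triangular bumps) is a caricature of
  fragment pileups; it suffices for metaprofile logic, not for peak-caller
  benchmarking.
* No replicate-aware statistics: recruitment is a single number per peak.
* The slope of the binned curve depends on the calling threshold when noise
  is large (threshold selection flattens the low-recruitment end); recovery
  guarantees hold in the low-noise regime.
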