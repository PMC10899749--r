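# atpossess

Sequence-composition analysis of ChIP-seq peaks for AT-rich minor-groove
binders — H-NS-family xenogeneic silencers and their post-translationally
modified variants. The package asks, from peak calls alone, how firmly a
nucleoid-associated protein *possesses* AT-rich DNA, and how a modification
such as lysine acetylation erodes that possession.

It is aimed at bacterial regulatory genomicists who already have peak calls
(ENCODE narrowPeak), a genome FASTA, TSS annotations (BED6), coverage
(bedGraph) and qPCR Ct tables, and want the downstream composition
statistics.

## What it computes

For a peak set with summits and recruitment levels (fold enrichment, Fc):

- **Summit-window AT content** — per peak, the AT fraction of the window
  summit ± 49 bp, summarised against genome-wide and genomic-island AT%.
- **Oligonucleotide usage deviation** — overlapping dinucleotide and
  trinucleotide frequencies (16 and 64 categories) divided by the uniform
  expectation (0.0625 and 0.015625), and for each k-mer the Spearman rho
  (with p and BH q) between usage deviation and recruitment across peaks.
- **Binned AT-recruitment curve** — recruitment divided into 20 ranges;
  OLS slope of bin-mean AT% on bin-mean Fc. With recruitment modelled as
  `r = β(1−α)·max(0, a − a₀) + r₀(1+κα) + ε` (AT fraction `a`, background
  `a₀`, acetylation `α`), the curve's slope is `1/(β(1−α))` — it *steepens*
  as acetylation weakens specific binding.
- **TSS metaprofile** — a computeMatrix-style, strand-corrected signal
  matrix and mean profile of coverage around transcription start sites.
- **Differential peak comparison** — unique/shared peaks between two
  conditions with recruitment and AT% of the unique fraction.
- **ΔΔCt** — ChIP-qPCR enrichment normalized to a nonspecific `dnaA`
  locus, and qRT-PCR relative expression (`2^−ΔΔCt`).

A synthetic genome/occupancy/Ct simulator (`sim_config()`,
`simulate_genome()`, `simulate_peaks()`, `simulate_coverage()`,
`simulate_ct()`) generates data under exactly this model with recorded
ground truth, so every statistic is validated by parameter recovery.

## Worked example

```r
library(atpossess)

cfg0 <- sim_config(seed = 11, alpha_acetyl = 0)    # native silencer
cfg8 <- sim_config(seed = 11, alpha_acetyl = 0.8)  # acetylation mimic
g    <- simulate_genome(cfg0)
nat  <- simulate_peaks(cfg0, g)
ace  <- simulate_peaks(cfg8, g)

peakset_at_summary(nat$peaks, g, attr(g, "islands"))
#> AT summary (per_peak): peaks 50.85% (n=222) | genome 43.30% | islands 55.06%
peakset_at_summary(ace$peaks, g, attr(g, "islands"))
#> AT summary (per_peak): peaks 46.82% (n=212) | genome 43.30% | islands 55.06%

bin_at_vs_recruitment(nat$peaks, g)
#> AT-recruitment curve: 222 peaks in 20 bins (20 used)
#>   slope 0.5006 AT% per fold-enrichment unit (r_bins = 1.000)

co <- correlate_usage_recruitment(nat$peaks, g, k = 2)
co[co$kmer %in% c("AT", "TA", "CG", "GC"), c("kmer", "rho", "p")]
#>    kmer        rho            p
#> 4    AT  0.5978599 6.621489e-23
#> 7    CG -0.5931670 1.730004e-22
#> 10   GC -0.5642872 4.586626e-20
#> 13   TA  0.6476629 8.652863e-28
```

The native silencer's peaks are strongly AT-enriched over the genome, AT/TA
dinucleotide usage correlates positively (CG/GC negatively) with
recruitment, and the shallow slope (~0.5 AT% per fold) reflects firm
possession: small AT excesses already command high occupancy. Under the
acetylation mimic, peak AT% falls toward background and the slope steepens —
the protein spreads onto non-AT-rich DNA and needs a larger AT excess per
unit of recruitment.

File-based workflows use the same functions via readers/writers
(`read_fasta`, `read_narrowpeak`, `read_bed_tss`, `read_bedgraph`,
`write_tsv`, ...) or the thin CLI in `inst/scripts/atpossess.R`
(subcommands `simulate`, `validate`, `peak-at`, `atmap`, `oligo`, `corr`,
`curve`, `tssprofile`, `qpcr`).

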