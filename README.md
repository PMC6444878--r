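# nucshift

Nucleosome occupancy profiling and differential shift analysis for
paired-end MNase-Seq, for chromatin biologists comparing nucleosome
organization between two conditions (for example a control and a chromatin
regulator knockdown). The package covers the full desk-side pipeline:
fragment I/O, depth-normalized occupancy tracks, TSS-oriented average
profiles and heatmaps, fragment-length and 2D length-by-position matrices,
nucleosome calling with fuzziness scores, a signed per-base
positional-difference statistic, cross-condition matching of +1/−1
nucleosomes with shift-bin classification, phasing/spacing/variance
statistics, dinucleotide and k-mer sequence profiling, and association of
shift groups with external signal densities and differential expression —
plus a synthetic chromatin simulator with programmable ground truth so
every stage is testable without external data.

## The model in brief

MNase digestion leaves ~147 bp of nucleosome-wrapped DNA; each sequenced
fragment is summarized by its **dyad** (center base,
`floor((start + end − 1)/2)`). Per-base dyad counts are normalized to
**RPBM** (reads per base per million mapped reads),

```
RPBM(x) = count(x) × 10^6 / N_total ,
```

smoothed with a unit-mass gaussian kernel (σ = 20 bp), and nucleosomes are
called at local maxima with a 147-bp footprint (summit ± 73) and a
fuzziness score (SD of supporting dyads). Fragments of 140–180 bp are
treated as canonical mononucleosomes. Between conditions A (control) and
B (treatment):

- **Positional difference** per base: windowed dyad counts with a
  pseudocount of 1 on both sides are compared with the exact conditional
  test for two Poisson counts (binomial on the B count given the window
  total, p = N_B/(N_A+N_B)); the track stores −log10 p where A exceeds
  depth-scaled B and +log10 p (negative) where B exceeds A, and is exactly
  antisymmetric under swapping the conditions.
- **Nucleosome variance** of a region: mean |summit_B − summit_A| over
  footprint-overlapping one-to-one matched nucleosome pairs.
- **Shift classification**: the gene-oriented shift of each +1/−1
  nucleosome is binned into 0, 1–9, 10–50, 51–100, 101–150, 151–200 bp with
  an upstream/downstream direction; shifts beyond 200 bp are excluded.
- **Phasing**: a TSS profile is canonical when it has a nucleosome-depleted
  region (NDR) upstream of the TSS, a prominent +1 peak, and downstream
  peaks with decaying amplitude; the array period is the mean peak-to-peak
  distance.

The simulator generates phased arrays (default spacing 190 bp, NDR 150 bp,
+1 dyad 100 bp downstream of the TSS), programs known +1/−1 dyad shifts
into condition B, and samples fragments with configurable length
distribution (147 ± 12 bp), dyad jitter, and depth.

## Worked example

```r
library(nucshift)

cfg <- default_config(seed = 7, outdir = "demo_out")
cfg$simulate$n_genes  <- 40
cfg$simulate$chrom_len <- 280000
res <- run_pipeline(cfg, "all")      # simulate -> ... -> integrate

st <- read.delim("demo_out/shift_table.tsv")
table(st$bin[st$role == 1])
#>       0     1-9   10-50 101-150 151-200  51-100
#>       3      17       6       4       4       6

read.delim("demo_out/shift_summary.tsv")
#>               metric      value
#> 1            n_pairs 234.000000
#> 2 region_variance_bp   5.769231
#> 3    spacing_mode_bp 189.000000
#> 4     spacing_iqr_bp   6.000000
```

Half of the 40 genes carry programmed +1 shifts of 30/75/125/175 bp, and
the bin table recovers them: unprogrammed genes land in the 0 / 1–9 bins
(summit estimation noise of a few bp), and the four programmed magnitudes
fill the 10–50 through 151–200 bins. The 234 matched nucleosome pairs have
a mean cross-condition displacement (nucleosome variance) of 5.8 bp —
most nucleosomes are stable — and adjacent summits sit at a modal spacing
of 189 bp with a 6-bp IQR, reflecting the simulated 190-bp phased arrays.
`demo_out/` also contains bedGraph occupancy and positional-difference
tracks, TSS profiles, the dinucleotide composition profile, and the
DE-association table; `manifest.tsv` lists every file with its checksum
(two runs with the same config and seed are byte-identical).

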