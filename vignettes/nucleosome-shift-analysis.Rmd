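---
title: "Methods: nucleosome occupancy and differential shift analysis"
author: "nucshift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: nucleosome occupancy and differential shift analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucshift)
```

## Scope and data model

`nucshift` compares nucleosome organization between two paired-end
MNase-Seq conditions. The atomic observation is a protected fragment
`[start, end)` in 0-based half-open (BED) coordinates; all anchor points
(TSS, DHS, CTCF/TF sites) are single base pairs in the same convention,
which removes the ±1 ambiguities that plague mixed-convention pipelines.
The nucleosome position estimate is the **dyad**, the center base of the
fragment, `floor((start + end − 1)/2)`. For odd fragment lengths (147 bp,
the biological default) this midpoint is exact and mirror-symmetric; for
even lengths it rounds half a base toward the start, a deterministic
choice that makes all downstream arithmetic reproducible. Genome
mirroring is therefore exactly self-consistent for odd-length fragments,
which is how the orientation-symmetry tests are constructed.

Depth normalization uses RPBM (reads per base per million mapped reads):
each per-base count is scaled by `1e6 / total_count`, where `total_count`
is the number of parsed fragment records *before* any length filtering.
Keeping the denominator fixed makes RPBM values comparable across
length-filter settings (canonical 140–180 bp versus all fragments) and
makes duplication of the entire library an exact no-op. Exact-coordinate
deduplication is available but off by default: redundant-read removal
belongs to the upstream mapping step, and applying it again here would
silently change the denominator semantics.

## Occupancy tracks, profiles, and matrices

Occupancy is accumulated in dyad mode (one count at each fragment's dyad;
genome-wide integral = fragment count) or coverage mode (one count per
covered base). Profiles default to dyad mode, which preserves the phasing
structure that footprint coverage blurs. Smoothing is discrete
convolution with a unit-mass kernel — gaussian with σ = `bandwidth`
(truncated at 4σ) or triangular — with reflected edges, so total signal
is conserved to floating-point accuracy; bandwidth 0 is the identity. The
analysis default is a gaussian with σ = 20 bp: narrow enough to resolve
adjacent nucleosomes down to ~45 bp separation, wide enough to merge the
per-base sampling noise of a 50-fragment cluster into a single summit.

Average profiles around anchors are strand-oriented (minus-strand windows
are reversed) and drop anchors whose window leaves the chromosome rather
than zero-padding them, which would bias edge means. Heatmaps order
anchors by a caller-supplied sort key with name-lexicographic
tie-breaking, so row order is fully deterministic and row means always
reproduce the average profile. The 2D occupancy matrix bins dyad counts
by fragment length (bounded support 100–250 bp, matching a
mononucleosome gel cut) and strand-oriented offset; its column sums are
by construction identical to the 1D dyad profile of the same
length-restricted fragments, a checked invariant.

## Nucleosome calling

Summits are plateau-aware local maxima of the smoothed RPBM track: a run
of equal values strictly above both flanking values counts as one summit
at its (left-of-)center base. Plateau handling matters in noise-free
data, where two equal point clusters at even separation would otherwise
produce no strict maximum at all. Candidate summits below
`min_occupancy` (default 1 RPBM) are discarded; the rest are retained
greedily by descending occupancy, leftmost first on ties, subject to a
minimum summit separation. The footprint is fixed at 147 bp
(summit ± 73), the canonical length of octamer-wrapped DNA; fuzziness is
the sample SD of the dyads inside the footprint (undefined below two
dyads).

The default `min_summit_distance` is 55 bp. This was a genuinely open
design point: a separation near the footprint size (~120 bp) suppresses
duplicate calls aggressively but cannot represent two nucleosomes whose
spacing has collapsed — exactly what a 100–175 bp positional shift does
to the +1 nucleosome and its neighbor (spacing 190 bp minus the shift).
With σ = 20 bp smoothing and ~10 bp dyad jitter, two equal clusters
65 bp apart have an expected smoothed mode separation of ≈63 bp, so a
60 bp threshold sits on the boundary and sampling noise occasionally
removes a true summit; 55 bp leaves margin, while single-cluster
shoulders 55 bp from a summit are ~5 % of peak height and fall below the
occupancy floor, so fission of single nucleosomes is not observed in the
simulated regimes. Clusters closer than ~45 bp are unimodal after
smoothing and are intentionally reported as one merged summit near the
midpoint; the shift classifier accounts for this (below).

## Positional difference between conditions

Per base, dyad counts are summed over a centered window (default 147 bp)
in each condition and a pseudocount of 1 is added on both sides. The
counts are compared with the exact conditional test for two Poisson
rates: conditional on the window total `n = a + b`, the B count is
binomial with success probability `N_B / (N_A + N_B)`, and the two-sided
p-value doubles the smaller tail (capped at 1). This is the exactly
computable member of the Poisson-comparison family, and the two tails
are evaluated in a form symmetric in the two conditions
(`P(X ≥ b) = P(n − X ≤ a)`), so `diff(A, B) = −diff(B, A)` holds
bit-exactly rather than approximately. The score convention is
`−log10 p` (positive) where A exceeds depth-scaled B and `+log10 p`
(negative) where B exceeds A; equal scaled counts score 0. No per-base
multiple-testing correction is applied — the track is a signed evidence
display, not a set of discoveries.

## Cross-condition matching and shift classification

Nucleosome variance follows the overlapping-pair definition: candidate
pairs are A/B calls whose 147-bp footprints intersect
(|Δsummit| ≤ 146), matched one-to-one greedily by ascending |Δ| with
leftmost-A tie-breaking (deterministic and order-independent), and a
region's variance is the mean absolute pair distance.

Roles are assigned on the control calls — +1 is the nearest call at or
downstream of the TSS in gene orientation, −1 the nearest strictly
upstream, each within 1 kb — and the matched treatment call inherits the
role. Shifts are classified by |gene-oriented shift| into the strata
0, 1–9, 10–50, 51–100, 101–150, 151–200 bp with a downstream/upstream
direction; beyond 200 bp the pair is excluded and counted separately
(the ±200 bp stratification is treated as a hard exclusion, with the
excluded count reported, since the alternative axis-limit reading cannot
be distinguished from the source material).

Shifts in (146, 200] exceed single-footprint overlap, and large shifts
can merge the moved nucleosome into its neighbor's call entirely. When a
control ±1 call is left unpaired, a secondary match searches condition-B
summits within 200 bp: candidates with occupancy below 75 % of the best
candidate are discarded — a summit that absorbed a shifted neighbor
carries roughly twice the occupancy of an ordinary call, and the 75 %
cutoff separates that ~2× regime from ~1× noise — and the nearest of the
comparable candidates wins. A plain nearest-summit rule mispicks the
unshifted −1 neighbor in the large-downstream-shift geometry; a plain
highest-occupancy rule mispicks on occupancy noise whenever no merged
call exists; the combined rule handles both, and recovers 100 % of
programmed bins and directions in the simulated study conditions.

Spacing is summarized as adjacent summit-to-summit distances, with
uniformness reported as the 1-bp-histogram mode (smallest value on ties)
and the type-7 (linear interpolation) interquartile range. Phasing
metrics operate on an already-smoothed profile: peaks are local maxima
above 20 % of the profile maximum; the +1 peak is the first downstream
peak; NDR depth is the profile minimum in [−250, +50] divided by the +1
height; the array period is the mean successive downstream peak
distance. A profile is canonical when the NDR depth ratio is below 0.5,
a +1 peak exists, and downstream amplitudes are non-increasing within a
5 % tolerance.

## Sequence features

Dinucleotide composition around dyads uses the weak class
{AA, AT, TA, TT} and, by default, the strong class {GC, CG} (the common
printed convention), with the full {GG, GC, CG, CC} set available;
windows are strand-oriented (reverse-complemented for minus sites),
sites whose window leaves the chromosome are dropped and counted, and
dinucleotides containing ambiguity codes leave the denominator at that
offset. Positional k-mer counting (default 6-mers in 10-bp bins tiling
±130 bp, with 125 bp available — both flank conventions are in use) bins
each k-mer by its start offset and z-scores per-k-mer frequencies across
bins. Genic annotation uses a promoter of 1 kb upstream to 100 bp
downstream of the TSS in gene orientation, the remainder of [TSS, TES]
as gene body, promoter winning on overlap.

## Integration

Signal quantification counts tag dyads per region and reports
RPBM-scaled densities with a log2(x + 1) display transform (the offset
of 1 keeps zero regions at 0). Group distributions are compared with the
two-sample two-sided Kolmogorov–Smirnov test via `stats::ks.test`, exact
(permutation-equivalent) when both samples have ≤ 10 observations;
quartile summaries are type 7 throughout. Differential-expression status
uses log2FC ≥ log2(1.5) and FDR < 0.001 by default; genes absent from
the DE table count as unchanged with the number reported. "Bound"
nucleosomes are those whose summit lies inside a bound region (summit
membership is deterministic; footprint-overlap mode is available), and
enrichment is the bound fraction of each shift group over the 0-bp
reference group.

## The simulator and what passing tests mean

The generator emulates the promoter architecture the analysis targets:
non-overlapping genes with random strand on one chromosome, a +1 dyad
100 bp downstream of the TSS, an NDR of 150 bp between the −1 and +1
dyads, and phased arrays at 190 bp spacing on both sides. Programmed
shifts move only the ±1 dyads of condition B (downstream arrays do not
co-shift by default, keeping recovery unambiguous). Fragments are drawn
per truth dyad with gaussian center jitter (default SD 10 bp) and
gaussian lengths 147 ± 12 bp clamped to [100, 250]; the dispersion
values are simulation conventions chosen to look like a good
mononucleosome preparation, not measured quantities. GC content can be
elevated under footprints to give the composition profiler a recoverable
signal. The study conditions used by the acceptance checks are 200
genes, 50 fragments per nucleosome, shifts of 30/75/125/175 bp half
downstream and half upstream — sizes chosen so the full suite runs in
tens of seconds on one CPU.

The simulator deliberately omits sequencing error, PCR duplicates, MNase
sequence preference, partial unwrapping, and multi-modal dyad clusters.
Passing tests therefore demonstrate that the estimators are correct and
well-calibrated under idealized sampling noise; they do not demonstrate
robustness to MNase digestion bias or to the heterogeneous occupancy of
real chromatin, where parameter defaults (occupancy floor, summit
separation) may need adjustment.

## Numerical choices and degenerate inputs

Ties are broken deterministically everywhere: descending-occupancy then
leftmost for summits, ascending |shift| then leftmost-A for pairs,
name-lexicographic for heatmap rows, smallest value for spacing modes.
Degenerate inputs fail loudly rather than silently: empty fragment
files, zero usable anchors, empty dyad sets, nonpositive library sizes,
and zero-length regions all raise errors; an empty canonical-filter
result is valid until a downstream stage needs fragments. bedGraph
values are written at full double precision (`%.17g`) so write/read
round trips are bit-exact, which is what makes the pipeline's
manifest-checksum determinism contract testable. All pipeline stages
derive their RNG streams from the single config seed, so one integer
reproduces the entire study.
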