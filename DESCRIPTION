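Package: nucshift
Title: Nucleosome Occupancy Profiling and Differential Shift Analysis for MNase-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for comparing nucleosome organization between two
    MNase-Seq conditions. Builds dyad/coverage occupancy tracks with RPBM
    normalization, computes anchor-oriented average profiles, sorted heatmaps,
    fragment-length densities and 2D length-by-position occupancy matrices,
    calls positioned nucleosomes with fuzziness scores, computes a signed
    per-base positional-difference statistic, matches nucleosomes across
    conditions to classify +1/-1 shifts by distance bin and gene-oriented
    direction, derives phasing, spacing and variance statistics, profiles
    AT/GC dinucleotide composition and positional k-mers around dyads, and
    integrates shift groups with external signal densities and differential
    expression. Includes a synthetic chromatin simulator with programmable
    ground-truth dyad shifts so every stage is testable end-to-end.
License: MIT
Encoding: UTF-8
Imports:
    Biostrings,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
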