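# Shared fixture builders; everything is generated in code at test time.

tmpfile <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

# A small FragmentSet built directly from coordinates.
make_frags <- function(start, end, chrom = "c1", total = length(start),
                       label = "t") {
  fragment_set(data.frame(chrom = rep_len(chrom, length(start)),
                          start = start, end = end),
               total_count = total, sample_label = label)
}

# Mirror all coordinates through a chromosome of length L (0-based).
mirror_frags <- function(frags, L) {
  df <- frags$fragments
  fragment_set(data.frame(chrom = df$chrom, start = L - df$end,
                          end = L - df$start),
               total_count = frags$total_count,
               sample_label = frags$sample_label)
}

mirror_anchors <- function(anchors, L) {
  out <- anchors
  out$position <- L - 1L - anchors$position
  out$strand <- ifelse(anchors$strand == "+", "-", "+")
  out
}

revcomp_chr <- function(s)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))

# Standard small study: simulated genome + programmed +1 shifts + sampled
# fragments for both conditions, with calls.
run_small_study <- function(n_genes = 40, seed = 11, jitter = 10,
                            len_sd = 12, depth = 50,
                            deltas = c(30, 75, 125, 175)) {
  model <- simulate_genome(n_genes = n_genes, chrom_len = n_genes * 7000,
                           seed = seed)
  model <- program_shifts(model, make_shift_programs(model, deltas = deltas,
                                                     fraction = 0.5,
                                                     seed = seed + 1))
  clen <- stats::setNames(model$chrom_len, model$chrom)
  calls <- lapply(c(A = "A", B = "B"), function(cond) {
    fr <- sample_fragments(model, cond, depth_per_nuc = depth,
                           len_sd = len_sd, dyad_jitter_sd = jitter,
                           seed = seed + match(cond, c("A", "B")))
    can <- filter_canonical(fr, 100, 250)
    tr <- smooth_track(rpbm_normalize(dyad_density(can, chrom_lengths = clen)), 20)
    call_nucleosomes(tr, min_occupancy = 1, min_summit_distance = 55,
                     frags = can, sample_label = cond)
  })
  list(model = model, calls_A = calls$A, calls_B = calls$B)
}

# Score +1 shift-bin recovery of a study against its programmed truth.
score_recovery <- function(study) {
  st <- gene_shift_table(study$calls_A, study$calls_B, study$model$genes)
  tr <- study$model$truth
  prog <- tr[tr$condition == "B" & tr$delta > 0 & tr$role == 1, ]
  m <- merge(st[st$role == 1, ], prog[, c("gene_id", "delta", "direction")],
             by = "gene_id", suffixes = c("", ".true"))
  m$true_bin <- classify_shift(ifelse(m$direction.true == "downstream",
                                      m$delta, -m$delta))$bin
  list(n = nrow(m),
       bin_acc = mean(m$bin == m$true_bin),
       dir_acc = mean(m$direction == m$direction.true),
       table = m)
}
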