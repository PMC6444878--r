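calls_df <- function(summit, chrom = "c1", occupancy = 10, label = "A") {
  data.frame(chrom = chrom, summit = as.integer(summit),
             start = as.integer(summit - 73), end = as.integer(summit + 74),
             occupancy = occupancy, fuzziness = NA_real_,
             sample_label = label, stringsAsFactors = FALSE)
}

test_that("flanking nucleosome roles are gene-oriented", {
  genes <- data.frame(gene_id = c("g1", "g2"), chrom = "c1",
                      strand = c("+", "-"), tss = c(5000L, 5000L))
  calls <- calls_df(c(4800, 5150, 5330, 4850))
  r <- assign_flanking_nucleosomes(calls, genes[1, ])
  expect_equal(r$summit[r$role == 1], 5150)
  expect_equal(r$summit[r$role == -1], 4850) # closest upstream
  # minus strand flips orientation
  r2 <- assign_flanking_nucleosomes(calls_df(c(4850, 5200)), genes[2, ])
  expect_equal(r2$summit[r2$role == 1], 4850)
  expect_equal(r2$summit[r2$role == -1], 5200)
  # missing slot within the window
  r3 <- assign_flanking_nucleosomes(calls_df(5150), genes[1, ])
  expect_true(is.na(r3$summit[r3$role == -1]))
  expect_equal(r3$summit[r3$role == 1], 5150)
})

test_that("pairing requires footprint overlap and minimizes |shift| greedily", {
  p <- pair_nucleosomes(calls_df(1000), calls_df(1060))
  expect_equal(p$shift_genomic, 60)
  p2 <- pair_nucleosomes(calls_df(1000), calls_df(1200))
  expect_equal(nrow(p2), 0)
  expect_equal(attr(p2, "unpaired_A"), 1L)
  p3 <- pair_nucleosomes(calls_df(1000), calls_df(c(1010, 1100)))
  expect_equal(nrow(p3), 1)
  expect_equal(p3$summit_B, 1010)
  # stability under input order permutation
  set.seed(6)
  a <- calls_df(sort(sample(seq(1000, 40000, by = 40), 60)))
  b <- calls_df(a$summit + sample(-120:120, 60, replace = TRUE))
  p_fwd <- pair_nucleosomes(a, b)
  perm <- sample(nrow(b))
  p_perm <- pair_nucleosomes(a, b[perm, ])
  expect_equal(p_fwd[, c("summit_A", "summit_B")],
               p_perm[, c("summit_A", "summit_B")])
})

test_that("region variance equals the brute-force pair-distance mean", {
  p <- data.frame(shift_genomic = c(10, -20, 30))
  expect_equal(region_variance(p), 20)
  expect_equal(region_variance(data.frame(shift_genomic = 0)), 0)
  expect_true(is.na(region_variance(p[0, , drop = FALSE])))
  set.seed(14)
  for (r in 1:5) {
    sh <- sample(-200:200, sample(2:40, 1), replace = TRUE)
    brute <- sum(abs(sh)) / length(sh)
    expect_equal(region_variance(data.frame(shift_genomic = sh)), brute)
  }
})

test_that("shift classification uses the standard bins and directions", {
  cl <- classify_shift(c(75, -160, 0, 5, -9, 10, 50, 51, 100, 101, 150,
                         151, 200, 201, -250))
  expect_equal(cl$bin, c("51-100", "151-200", "0", "1-9", "1-9", "10-50",
                         "10-50", "51-100", "51-100", "101-150", "101-150",
                         "151-200", "151-200", "excluded", "excluded"))
  expect_equal(cl$direction[1:3], c("downstream", "upstream", "none"))
})

test_that("spacing distances and uniformness summarize adjacent summits", {
  sp <- spacing_distances(calls_df(c(1000, 1190, 1375)))
  expect_setequal(sp$distances, c(190, 185))
  expect_equal(sum(sp$density$density), 1)
  expect_equal(nrow(spacing_distances(calls_df(1000))$density), 0)
  # uniform synthetic array: point mass
  sp2 <- spacing_distances(calls_df(seq(1000, 2900, by = 190)))
  expect_equal(unique(sp2$distances), 190)
  u <- uniformness(sp2$distances)
  expect_equal(u$mode, 190)
  expect_equal(u$iqr, 0)
  # type-7 quartiles and smallest-value mode tie-break
  u2 <- uniformness(c(180, 185, 190, 195, 200))
  expect_equal(u2$mode, 180)
  expect_equal(u2$iqr, 10)
  expect_true(is.na(uniformness(numeric(0))$mode))
})

test_that("phasing metrics recover a decaying cosine array and reject flat", {
  off <- -1000:1000
  period <- 190
  ndr <- 1 - 0.9 * exp(-((off + 100) / 120)^2) # deep dip upstream of +1
  arr <- ifelse(off > 0, (0.5 + 0.5 * cos(2 * pi * (off - 100) / period)) *
                  exp(-off / 700), 0.15)
  prof <- structure(list(offsets = off, mean_density = arr * ndr + 0.05,
                         n_anchors = 100, units = "RPBM"),
                    class = "Profile1D")
  pm <- phasing_metrics(prof)
  expect_true(pm$canonical)
  expect_true(pm$decay_monotone)
  expect_lt(abs(pm$period - period), 5)
  expect_lt(abs(pm$plus1_offset - 100), 10)
  # flat profile: no peaks, not canonical
  flat <- structure(list(offsets = off, mean_density = rep(1, length(off)),
                         n_anchors = 10, units = "RPBM"),
                    class = "Profile1D")
  pf <- phasing_metrics(flat)
  expect_false(pf$canonical)
  expect_length(pf$peak_offsets, 0)
  # rising downstream amplitudes break monotone decay
  rising <- prof
  rising$mean_density <- ifelse(off > 0,
                                (0.5 + 0.5 * cos(2 * pi * (off - 100) / period)) *
                                  exp(off / 1500), 0.15) * ndr + 0.05
  pr <- phasing_metrics(rising)
  expect_false(pr$decay_monotone)
  expect_false(pr$canonical)
})

test_that("gene shift tables recover programmed +1 shifts", {
  study <- run_small_study(n_genes = 32, seed = 19)
  sc <- score_recovery(study)
  expect_gte(sc$n, 10)
  expect_gte(sc$bin_acc, 0.9)
  expect_equal(sc$dir_acc, 1)
})

test_that("bin and direction labels are invariant under genome mirroring", {
  study <- run_small_study(n_genes = 20, seed = 29)
  st <- gene_shift_table(study$calls_A, study$calls_B, study$model$genes)
  L <- study$model$chrom_len
  mirror_calls <- function(calls) {
    out <- calls
    out$summit <- L - 1L - calls$summit
    out$start <- L - calls$end
    out$end <- L - calls$start
    out[order(out$summit), ]
  }
  genes_m <- study$model$genes
  genes_m$tss <- L - 1L - genes_m$tss
  genes_m$tes <- L - 1L - genes_m$tes
  genes_m$strand <- ifelse(genes_m$strand == "+", "-", "+")
  st_m <- gene_shift_table(mirror_calls(study$calls_A),
                           mirror_calls(study$calls_B), genes_m)
  key <- paste(st$gene_id, st$role)
  key_m <- paste(st_m$gene_id, st_m$role)
  m <- match(key, key_m)
  expect_equal(st_m$bin[m], st$bin)
  expect_equal(st_m$direction[m], st$direction)
  expect_equal(st_m$shift_oriented[m], st$shift_oriented)
})
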