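test_that("canonical filtering keeps 140-180 bp and the input total", {
  lens <- c(120, 140, 150, 180, 200)
  fs <- make_frags(seq(0, by = 1000, length.out = 5),
                   seq(0, by = 1000, length.out = 5) + lens, total = 7)
  can <- filter_canonical(fs)
  expect_setequal(can$fragments$length, c(140, 150, 180))
  expect_equal(can$total_count, 7)
  expect_equal(filter_canonical(fs, 0, Inf)$fragments, fs$fragments)
  expect_error(filter_canonical(fs, 180, 140), "lo must not exceed hi")
  # empty result is allowed; downstream density then errors cleanly
  none <- filter_canonical(fs, 300, 400)
  expect_equal(nrow(none$fragments), 0)
  expect_error(fragment_length_density(none), "no fragments")
})

test_that("summit calling recovers clean dyad clusters and applies the greedy rule", {
  # two noiseless clusters at 5100 and 5290
  st <- c(rep(5100 - 73, 40), rep(5290 - 73, 40))
  fs <- make_frags(st, st + 147, total = 80)
  tr <- smooth_track(rpbm_normalize(dyad_density(fs, chrom_lengths = c(c1 = 8000))), 20)
  calls <- call_nucleosomes(tr, min_occupancy = 1, min_summit_distance = 55)
  expect_equal(nrow(calls), 2)
  expect_true(all(abs(sort(calls$summit) - c(5100, 5290)) <= 2))
  expect_equal(calls$end - calls$start, c(147, 147))
  # flat zero track: no calls
  flat <- occupancy_track(list(c1 = numeric(500)), smoothing = 5)
  expect_equal(nrow(call_nucleosomes(flat)), 0)
  # two maxima 50 bp apart with min_summit_distance 120: higher kept
  v <- numeric(1000)
  v[301] <- 5; v[351] <- 7
  v <- smooth_track(occupancy_track(list(c1 = v)), 5)$values$c1
  tr2 <- occupancy_track(list(c1 = v), smoothing = 5)
  calls2 <- call_nucleosomes(tr2, min_occupancy = 0.001,
                             min_summit_distance = 120)
  expect_equal(nrow(calls2), 1)
  expect_equal(calls2$summit, 350)
  expect_warning(call_nucleosomes(occupancy_track(list(c1 = v))),
                 "unsmoothed")
})

test_that("plateau maxima yield one centered summit", {
  v <- c(0, 1, 3, 3, 3, 1, 0)
  tr <- occupancy_track(list(c1 = v), smoothing = 1)
  calls <- call_nucleosomes(tr, min_occupancy = 0.5)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$summit, 3) # 0-based center of the run at indices 3:5
})

test_that("caller recovery on a noiseless simulated genome is exact", {
  m <- simulate_genome(n_genes = 10, chrom_len = 80000, seed = 17)
  fr <- sample_fragments(m, "A", depth_per_nuc = 40, len_sd = 0,
                         dyad_jitter_sd = 0, seed = 18)
  tr <- smooth_track(rpbm_normalize(
    dyad_density(fr, chrom_lengths = stats::setNames(m$chrom_len, m$chrom))), 20)
  calls <- call_nucleosomes(tr, min_occupancy = 1, min_summit_distance = 55,
                            frags = fr)
  truth <- m$truth$dyad[m$truth$condition == "A"]
  err <- vapply(truth, function(d) min(abs(calls$summit - d)), numeric(1))
  expect_true(all(err <= 2))
  expect_equal(nrow(calls), length(truth)) # no spurious summits
  expect_true(all(calls$fuzziness == 0)) # all dyads identical per cluster
})

test_that("fuzziness is the sample sd of supporting dyads", {
  st <- c(100, 100, 100) - 73
  fs <- make_frags(st, st + 147)
  call <- data.frame(chrom = "c1", summit = 100L, start = 27L, end = 174L)
  expect_equal(call_fuzziness(call, fs), 0)
  st2 <- c(98, 100, 102) - 73
  fs2 <- make_frags(st2, st2 + 147)
  expect_equal(call_fuzziness(call, fs2), 2) # sd of {98,100,102}
  fs3 <- make_frags(100 - 73, 100 + 74)
  expect_true(is.na(call_fuzziness(call, fs3)))
})

test_that("positional difference follows the sign convention and is antisymmetric", {
  mk <- function(counts, total) {
    occupancy_track(list(c1 = as.numeric(counts)), total_count = total)
  }
  # identical tracks, equal totals: zero everywhere
  a <- mk(c(0, 3, 10, 3, 0), 100)
  d <- positional_difference(a, mk(c(0, 3, 10, 3, 0), 100), window = 3)
  expect_true(all(d$values$c1 == 0))
  # B far above A: negative score
  d2 <- positional_difference(mk(c(0, 0, 0), 1000), mk(c(0, 30, 0), 1000),
                              window = 1)
  expect_lt(d2$values$c1[2], 0)
  # antisymmetry on random data
  set.seed(12)
  va <- rpois(400, 2)
  vb <- rpois(400, 3)
  A <- mk(va, 900); B <- mk(vb, 1300)
  dAB <- positional_difference(A, B, window = 25)$values$c1
  dBA <- positional_difference(B, A, window = 25)$values$c1
  expect_identical(dAB, -dBA)
  expect_error(positional_difference(A, B, totalA = 0, totalB = 10),
               "positive")
})

test_that("positional difference magnitudes match brute-force tail sums", {
  # oracle: exact conditional two-Poisson test, tails summed term by term
  oracle_p <- function(wa, wb, totalA, totalB) {
    a <- wa + 1; b <- wb + 1
    n <- a + b
    pB <- totalB / (totalA + totalB)
    terms <- vapply(0:n, function(k)
      exp(lchoose(n, k) + k * log(pB) + (n - k) * log(1 - pB)), numeric(1))
    lo <- sum(terms[0:b + 1])
    hi <- sum(terms[b:n + 1])
    min(1, 2 * min(lo, hi))
  }
  mk <- function(count, total)
    occupancy_track(list(c1 = c(0, count, 0)), total_count = total)
  # the worked example: A=2, B=20, equal totals
  d <- positional_difference(mk(2, 1e4), mk(20, 1e4), window = 1)$values$c1[2]
  expect_equal(abs(d), -log10(oracle_p(2, 20, 1e4, 1e4)))
  expect_lt(d, 0)
  set.seed(31)
  for (r in 1:20) {
    wa <- rpois(1, 8); wb <- rpois(1, 8)
    ta <- sample(1000:5000, 1); tb <- sample(1000:5000, 1)
    d <- positional_difference(mk(wa, ta), mk(wb, tb),
                               window = 1)$values$c1[2]
    expect_equal(abs(d), -log10(oracle_p(wa, wb, ta, tb)), tolerance = 1e-12)
  }
})

test_that("duplicating both libraries preserves signs and strengthens scores", {
  mk <- function(v, total) occupancy_track(list(c1 = v), total_count = total)
  set.seed(23)
  va <- as.numeric(rpois(200, 2)); vb <- as.numeric(rpois(200, 2))
  d1 <- positional_difference(mk(va, 500), mk(vb, 700), window = 15)$values$c1
  d2 <- positional_difference(mk(2 * va, 1000), mk(2 * vb, 1400),
                              window = 15)$values$c1
  nz <- d1 != 0
  expect_true(all(sign(d2[nz]) == sign(d1[nz])))
  expect_true(all(abs(d2) >= abs(d1) - 1e-9))
})
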