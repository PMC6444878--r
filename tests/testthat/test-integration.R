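test_that("signal quantification is RPBM-exact, additive, and depth-invariant", {
  pts <- data.frame(chrom = "c1", position = c(10L, 20L, 30L, 40L, 50L, 500L))
  regions <- data.frame(chrom = "c1", start = 0L, end = 100L)
  q <- quantify_signal(pts, regions, total = 1e6)
  expect_equal(q$count, 5)
  expect_equal(q$rpbm, 5)
  # zero tags: rpbm 0, log2 of the pseudocount
  q0 <- quantify_signal(pts, data.frame(chrom = "c1", start = 1000L,
                                        end = 1100L), total = 1e6)
  expect_equal(q0$rpbm, 0)
  expect_equal(q0$log2_rpbm, 0)
  # duplication invariance
  fs <- make_frags(c(10, 20, 600), c(157, 167, 747), total = 10)
  fs2 <- make_frags(rep(c(10, 20, 600), 2), rep(c(157, 167, 747), 2),
                    total = 20)
  r <- data.frame(chrom = "c1", start = 0L, end = 300L)
  expect_equal(quantify_signal(fs, r)$rpbm, quantify_signal(fs2, r)$rpbm)
  # additivity over disjoint regions
  r2 <- data.frame(chrom = "c1", start = c(0L, 300L), end = c(300L, 900L))
  qq <- quantify_signal(fs, r2)
  expect_equal(sum(qq$count),
               quantify_signal(fs, data.frame(chrom = "c1", start = 0L,
                                              end = 900L))$count)
  expect_error(quantify_signal(pts, data.frame(chrom = "c1", start = 5L,
                                               end = 5L)), "zero-length")
})

test_that("KS comparison handles identical, disjoint, and tiny samples", {
  k <- ks_compare(c(1, 2, 3), c(1, 2, 3))
  expect_equal(k$D, 0)
  expect_equal(k$p_value, 1)
  expect_equal(ks_compare(c(1, 2, 3), c(11, 12, 13))$D, 1)
  expect_error(ks_compare(numeric(0), 1), "empty")
})

test_that("small-sample KS p-values equal exhaustive enumeration", {
  # oracle: permutation distribution of D over all label assignments
  enum_p <- function(a, b) {
    pooled <- c(a, b)
    na <- length(a)
    ecdf_d <- function(x, y) {
      grid <- sort(unique(c(x, y)))
      max(abs(vapply(grid, function(g) mean(x <= g) - mean(y <= g),
                     numeric(1))))
    }
    d_obs <- ecdf_d(a, b)
    idx <- utils::combn(length(pooled), na)
    ds <- apply(idx, 2, function(i) ecdf_d(pooled[i], pooled[-i]))
    mean(ds >= d_obs - 1e-12)
  }
  set.seed(27)
  for (r in 1:6) {
    na <- sample(3:6, 1); nb <- sample(3:6, 1)
    a <- sample(seq(0, 100, by = 0.5), na) # distinct values, no ties
    b <- sample(setdiff(seq(0, 100, by = 0.5), a), nb)
    k <- ks_compare(a, b)
    expect_equal(k$p_value, enum_p(a, b), tolerance = 1e-10)
  }
})

test_that("group summaries use type-7 quartiles", {
  gs <- group_summary(c(1, 2, 3, 4, 5), rep("g", 5))
  expect_equal(gs$median, 3)
  expect_equal(gs$q1, 2)
  expect_equal(gs$q3, 4)
  gs1 <- group_summary(7, "g")
  expect_true(all(unlist(gs1[, c("min", "q1", "median", "q3", "max")]) == 7))
  empty <- group_summary(numeric(0), character(0), levels = "g")
  expect_equal(empty$n, 0)
  expect_true(is.na(empty$median))
  # sort-and-interpolate oracle on random data
  set.seed(16)
  for (r in 1:5) {
    v <- rnorm(sample(3:50, 1))
    gs <- group_summary(v, rep("x", length(v)))
    s <- sort(v)
    n <- length(s)
    interp <- function(p) {
      h <- (n - 1) * p + 1
      lo <- floor(h)
      s[lo] + (h - lo) * (s[min(lo + 1, n)] - s[lo])
    }
    expect_equal(gs$q1, interp(0.25))
    expect_equal(gs$median, interp(0.5))
    expect_equal(gs$q3, interp(0.75))
  }
})

test_that("DE association reports group fractions and the pooled 10-200 row", {
  st <- data.frame(
    gene_id = sprintf("g%02d", 1:20), role = 1L, strand = "+",
    summit_A = 0L, summit_B = 0L, shift_genomic = 0L, shift_oriented = 0L,
    bin = rep(c("0", "10-50", "51-100", "101-150"), each = 5),
    direction = rep(c("none", "downstream", "upstream", "downstream"),
                    each = 5),
    stringsAsFactors = FALSE)
  de <- data.frame(gene_id = sprintf("g%02d", 1:18),
                   status = c(rep("up", 4), rep("down", 2),
                              rep("unchanged", 12)))
  assoc <- de_shift_association(st, de)
  r0 <- assoc[assoc$bin == "0", ]
  expect_equal(r0$fraction_up, 0.8) # g1-g4 up of g1-g5
  expect_equal(r0$fraction_down, 0.2)
  pooled <- assoc[assoc$bin == "10-200", ]
  expect_equal(pooled$n, 15)
  # pooled row equals the member-weighted mean of its bins
  bins <- assoc[assoc$bin %in% c("10-50", "51-100", "101-150"), ]
  expect_equal(pooled$fraction_up,
               sum(bins$fraction_up * bins$n) / sum(bins$n))
  expect_equal(attr(assoc, "n_missing_de"), 2)
  expect_true(all(assoc$fraction_up + assoc$fraction_down <= 1))
  expect_true(all(assoc$fraction_up >= 0 & assoc$fraction_up <= 1))
})

test_that("binding enrichment compares shifted groups to the 0-bp reference", {
  pos <- data.frame(group = rep(c("10-200", "0"), each = 40),
                    chrom = "c1",
                    summit = c(seq(100, by = 50, length.out = 40),
                               seq(5000, by = 50, length.out = 40)))
  # bound regions covering 20 shifted and 10 stable summits
  bound <- data.frame(chrom = "c1",
                      start = c(75L, 4975L), end = c(1100L, 5500L))
  be <- binding_enrichment(pos, bound)
  expect_equal(be$fraction_bound[be$group == "10-200"], 0.5)
  expect_equal(be$fraction_bound[be$group == "0"], 0.25)
  expect_equal(be$fold_vs_reference[be$group == "10-200"], 2)
  # no bound regions: zero fractions, missing folds
  be0 <- binding_enrichment(pos, bound[0, ])
  expect_true(all(be0$fraction_bound == 0))
  expect_true(all(is.na(be0$fold_vs_reference)))
  # brute-force interval-stabbing oracle on random data
  set.seed(37)
  posr <- data.frame(group = sample(c("a", "0"), 60, replace = TRUE),
                     chrom = "c1", summit = sample(0:5000, 60))
  s <- sample(0:4500, 8)
  br <- data.frame(chrom = "c1", start = s, end = s + sample(50:400, 8))
  ber <- binding_enrichment(posr, br)
  brute <- vapply(posr$summit, function(x)
    any(br$start <= x & br$end > x), logical(1))
  for (g in ber$group)
    expect_equal(ber$fraction_bound[ber$group == g],
                 mean(brute[posr$group == g]))
})
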