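#' Assign +1 and -1 nucleosomes to genes
#'
#' In gene orientation, +1 is the called nucleosome with the smallest
#' downstream summit distance from the TSS (at or past the TSS) and -1 the
#' one with the smallest strictly-upstream distance, each within a search
#' window. Genes lacking a candidate get an NA slot.
#'
#' @param calls nucleosome call data.frame (one condition).
#' @param genes gene data.frame with `gene_id`, `chrom`, `strand`, `tss`.
#' @param window maximum summit-to-TSS distance in bp.
#' @return data.frame with one row per (gene, role in c(1, -1)): `gene_id`,
#'   `role`, `summit` (NA when missing), `call_idx` (row index into
#'   `calls`).
#' @export
assign_flanking_nucleosomes <- function(calls, genes, window = 1000) {
  out <- vector("list", nrow(genes))
  for (i in seq_len(nrow(genes))) {
    dirn <- if (genes$strand[i] == "+") 1L else -1L
    sel <- which(calls$chrom == genes$chrom[i])
    d <- (calls$summit[sel] - genes$tss[i]) * dirn # oriented distance
    down <- sel[d >= 0 & d <= window]
    up <- sel[d < 0 & d >= -window]
    plus1 <- if (length(down)) down[which.min((calls$summit[down] - genes$tss[i]) * dirn)] else NA_integer_
    minus1 <- if (length(up)) up[which.max((calls$summit[up] - genes$tss[i]) * dirn)] else NA_integer_
    out[[i]] <- data.frame(
      gene_id = genes$gene_id[i], role = c(1L, -1L),
      call_idx = c(plus1, minus1),
      summit = c(if (is.na(plus1)) NA_integer_ else calls$summit[plus1],
                 if (is.na(minus1)) NA_integer_ else calls$summit[minus1]),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Match nucleosome calls across two conditions
#'
#' Candidate pairs are calls whose 147-bp footprints overlap by at least
#' 1 bp (|summit difference| <= 146 by construction, or `max_shift` if
#' given). A one-to-one matching is built greedily by ascending absolute
#' shift, ties broken by leftmost condition-A summit, so the result is
#' deterministic and order-independent.
#'
#' @param calls_A,calls_B call data.frames for control and treatment.
#' @param max_shift maximum |summit_B - summit_A| for a candidate pair
#'   (default 146 bp = footprint overlap).
#' @return data.frame of pairs: `chrom`, `summit_A`, `summit_B`,
#'   `shift_genomic`, `idx_A`, `idx_B`, with unpaired call indices in
#'   attributes `unpaired_A` / `unpaired_B`.
#' @export
pair_nucleosomes <- function(calls_A, calls_B, max_shift = 146) {
  cand <- list()
  for (cm in intersect(unique(calls_A$chrom), unique(calls_B$chrom))) {
    ia <- which(calls_A$chrom == cm)
    ib <- which(calls_B$chrom == cm)
    if (!length(ia) || !length(ib)) next
    g <- expand.grid(a = ia, b = ib)
    sh <- calls_B$summit[g$b] - calls_A$summit[g$a]
    keep <- abs(sh) <= max_shift
    if (any(keep))
      cand[[cm]] <- data.frame(a = g$a[keep], b = g$b[keep],
                               shift = sh[keep])
  }
  empty <- data.frame(chrom = character(), summit_A = integer(),
                      summit_B = integer(), shift_genomic = integer(),
                      idx_A = integer(), idx_B = integer())
  if (!length(cand)) {
    attr(empty, "unpaired_A") <- seq_len(nrow(calls_A))
    attr(empty, "unpaired_B") <- seq_len(nrow(calls_B))
    return(empty)
  }
  cand <- do.call(rbind, cand)
  cand <- cand[order(abs(cand$shift), calls_A$summit[cand$a], cand$a, cand$b), ]
  used_a <- logical(nrow(calls_A))
  used_b <- logical(nrow(calls_B))
  take <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!used_a[cand$a[i]] && !used_b[cand$b[i]]) {
      take[i] <- TRUE
      used_a[cand$a[i]] <- TRUE
      used_b[cand$b[i]] <- TRUE
    }
  }
  sel <- cand[take, , drop = FALSE]
  pairs <- data.frame(chrom = calls_A$chrom[sel$a],
                      summit_A = calls_A$summit[sel$a],
                      summit_B = calls_B$summit[sel$b],
                      shift_genomic = sel$shift,
                      idx_A = sel$a, idx_B = sel$b,
                      stringsAsFactors = FALSE)
  pairs <- pairs[order(pairs$chrom, pairs$summit_A), ]
  rownames(pairs) <- NULL
  attr(pairs, "unpaired_A") <- which(!used_a)
  attr(pairs, "unpaired_B") <- which(!used_b)
  pairs
}

#' Mean positional variance of nucleosome pairs in a region
#'
#' Nucleosome variance is the distance between two overlapping nucleosomes
#' matched across conditions; a region's variance is the mean of the
#' absolute pair distances.
#'
#' @param pairs pair data.frame from [pair_nucleosomes()] (already
#'   restricted to the region of interest).
#' @return mean |shift| in bp, or `NA` with zero pairs.
#' @export
region_variance <- function(pairs) {
  if (is.null(pairs) || nrow(pairs) == 0) return(NA_real_)
  mean(abs(pairs$shift_genomic))
}

#' Classify oriented shifts into distance bins and directions
#'
#' Bins the absolute gene-oriented shift into the standard strata
#' 0, 1-9, 10-50, 51-100, 101-150, 151-200 bp; shifts beyond 200 bp are
#' labelled `"excluded"`. Direction is `"downstream"` for positive oriented
#' shifts, `"upstream"` for negative, `"none"` at zero.
#'
#' @param shift_oriented numeric vector of gene-oriented shifts in bp
#'   (positive = towards the gene body).
#' @return data.frame with `bin` and `direction` character columns.
#' @export
classify_shift <- function(shift_oriented) {
  d <- abs(shift_oriented)
  bin <- ifelse(d == 0, "0",
         ifelse(d <= 9, "1-9",
         ifelse(d <= 50, "10-50",
         ifelse(d <= 100, "51-100",
         ifelse(d <= 150, "101-150",
         ifelse(d <= 200, "151-200", "excluded"))))))
  direction <- ifelse(shift_oriented > 0, "downstream",
                      ifelse(shift_oriented < 0, "upstream", "none"))
  data.frame(bin = bin, direction = direction, stringsAsFactors = FALSE)
}

#' Shift-bin factor levels in display order
#' @param with_excluded include the `"excluded"` level.
#' @return character vector of bin labels.
#' @export
shift_bins <- function(with_excluded = TRUE) {
  b <- c("0", "1-9", "10-50", "51-100", "101-150", "151-200")
  if (with_excluded) c(b, "excluded") else b
}

#' Per-gene +1/-1 shift table between two conditions
#'
#' Roles are assigned on the control (A) calls; the paired treatment call
#' inherits the role. Pairing uses footprint overlap first
#' ([pair_nucleosomes()]); a control call left unpaired falls back to the
#' nearest condition-B summit within `max_shift` bp, so shifts in the
#' (146, 200] stratum remain classifiable. The signed shift is oriented by
#' gene strand and classified with [classify_shift()].
#'
#' @param calls_A,calls_B call data.frames for the two conditions.
#' @param genes gene data.frame (`gene_id`, `chrom`, `strand`, `tss`).
#' @param window role-assignment search window (bp).
#' @param max_shift maximum classifiable |shift| (bp).
#' @return data.frame: `gene_id`, `role`, `strand`, `summit_A`, `summit_B`,
#'   `shift_genomic`, `shift_oriented`, `bin`, `direction`. Genes whose role
#'   slot found no A call, or no B partner, carry NA summits and bin
#'   `"unmatched"`.
#' @export
gene_shift_table <- function(calls_A, calls_B, genes, window = 1000,
                             max_shift = 200) {
  roles <- assign_flanking_nucleosomes(calls_A, genes, window = window)
  pairs <- pair_nucleosomes(calls_A, calls_B)
  b_of_a <- rep(NA_integer_, nrow(calls_A))
  b_of_a[pairs$idx_A] <- pairs$idx_B
  roles$strand <- genes$strand[match(roles$gene_id, genes$gene_id)]
  summit_B <- rep(NA_integer_, nrow(roles))
  for (i in seq_len(nrow(roles))) {
    ai <- roles$call_idx[i]
    if (is.na(ai)) next
    bi <- b_of_a[ai]
    if (!is.na(bi)) {
      summit_B[i] <- calls_B$summit[bi]
    } else {
      # Secondary match for large shifts (no footprint overlap): a
      # nucleosome that shifted into its neighbour is absorbed into a
      # merged call carrying roughly twice the occupancy, so candidates
      # well below the best candidate's occupancy (< 75%) are discarded
      # as ordinary single nucleosomes; among comparable candidates the
      # nearest summit wins, ties to the leftmost.
      sel <- which(calls_B$chrom == calls_A$chrom[ai])
      if (length(sel)) {
        dd <- abs(calls_B$summit[sel] - calls_A$summit[ai])
        keep <- dd <= max_shift
        sel <- sel[keep]
        dd <- dd[keep]
        if (length(sel)) {
          comparable <- calls_B$occupancy[sel] >=
            0.75 * max(calls_B$occupancy[sel])
          sel <- sel[comparable]
          dd <- dd[comparable]
          j <- sel[order(dd, calls_B$summit[sel])[1]]
          summit_B[i] <- calls_B$summit[j]
        }
      }
    }
  }
  dirn <- ifelse(roles$strand == "+", 1L, -1L)
  shift_genomic <- summit_B - roles$summit
  shift_oriented <- shift_genomic * dirn
  cls <- classify_shift(ifelse(is.na(shift_oriented), 0, shift_oriented))
  cls$bin[is.na(shift_oriented)] <- "unmatched"
  cls$direction[is.na(shift_oriented)] <- NA_character_
  out <- data.frame(gene_id = roles$gene_id, role = roles$role,
                    strand = roles$strand, summit_A = roles$summit,
                    summit_B = summit_B, shift_genomic = shift_genomic,
                    shift_oriented = shift_oriented,
                    bin = cls$bin, direction = cls$direction,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Adjacent nucleosome spacing distances
#'
#' Successive summit-to-summit distances along each chromosome, with a
#' density normalized to 1.
#'
#' @param calls call data.frame (or any data.frame with `chrom`, `summit`).
#' @return list with `distances` (bp multiset) and `density` data.frame
#'   (`distance`, `count`, `density`); empty with fewer than two calls.
#' @export
spacing_distances <- function(calls) {
  dist <- integer(0)
  for (cm in unique(calls$chrom)) {
    s <- sort(calls$summit[calls$chrom == cm])
    if (length(s) >= 2) dist <- c(dist, diff(s))
  }
  if (!length(dist))
    return(list(distances = integer(0),
                density = data.frame(distance = integer(), count = integer(),
                                     density = numeric())))
  tb <- table(dist)
  list(distances = dist,
       density = data.frame(distance = as.integer(names(tb)),
                            count = as.integer(tb),
                            density = as.numeric(tb) / sum(tb)))
}

#' Phasing metrics of a TSS-oriented profile
#'
#' Detects peaks (strict local maxima above `peak_min_frac` of the profile
#' maximum), locates the +1 peak (first downstream peak), measures NDR depth
#' (profile minimum in [-250, +50] relative to the +1 peak height), checks
#' that downstream peak amplitudes decay, and estimates the array period as
#' the mean successive downstream peak distance. The profile is "canonical"
#' when an NDR is present (depth ratio below `ndr_threshold`), a +1 peak
#' exists, and downstream amplitudes are non-increasing within tolerance.
#'
#' @param profile a `Profile1D` (already smoothed).
#' @param expected_spacing_range informative bp pair recorded in the report.
#' @param peak_min_frac peak height floor as a fraction of the maximum.
#' @param ndr_threshold canonical NDR depth ratio ceiling.
#' @param decay_tol relative tolerance for the non-increasing amplitude
#'   check.
#' @return A `PhasingReport` list: `peak_offsets`, `plus1_offset`,
#'   `plus1_prominence`, `ndr_depth`, `period`, `decay_monotone`,
#'   `canonical`.
#' @export
phasing_metrics <- function(profile, expected_spacing_range = c(150, 230),
                            peak_min_frac = 0.2, ndr_threshold = 0.5,
                            decay_tol = 0.05) {
  v <- profile$mean_density
  off <- profile$offsets
  n <- length(v)
  mid <- 2:(n - 1)
  pk <- mid[v[mid] > v[mid - 1] & v[mid] > v[mid + 1]]
  pk <- pk[v[pk] >= peak_min_frac * max(v)]
  peak_offsets <- off[pk]
  down <- pk[off[pk] > 0]
  has_plus1 <- length(down) > 0
  plus1_offset <- if (has_plus1) off[down[1]] else NA_integer_
  plus1_height <- if (has_plus1) v[down[1]] else NA_real_
  ndr_sel <- off >= -250 & off <= 50
  ndr_min <- if (any(ndr_sel)) min(v[ndr_sel]) else NA_real_
  ndr_depth <- if (has_plus1 && plus1_height > 0) ndr_min / plus1_height else NA_real_
  hts <- v[down]
  decay_monotone <- length(hts) >= 2 &&
    all(hts[-1] <= hts[-length(hts)] * (1 + decay_tol))
  if (length(hts) == 1) decay_monotone <- TRUE
  period <- if (length(down) >= 2) mean(diff(off[down])) else NA_real_
  plus1_prominence <- if (has_plus1) plus1_height / mean(v) else NA_real_
  canonical <- isTRUE(has_plus1 && !is.na(ndr_depth) &&
                        ndr_depth < ndr_threshold && decay_monotone)
  structure(list(peak_offsets = peak_offsets, plus1_offset = plus1_offset,
                 plus1_prominence = plus1_prominence, ndr_depth = ndr_depth,
                 period = period, decay_monotone = decay_monotone,
                 canonical = canonical,
                 expected_spacing_range = expected_spacing_range),
            class = "PhasingReport")
}

#' Uniformness summary of a spacing distribution
#'
#' Mode from the 1-bp histogram (smallest distance on ties) and the
#' interquartile range with type-7 (linear interpolation) quartiles; a
#' narrower IQR indicates more uniform spacing.
#'
#' @param distances numeric vector of adjacent-nucleosome distances (bp).
#' @return list with `mode`, `iqr`, `n`; all `NA`/0 when empty.
#' @export
uniformness <- function(distances) {
  if (!length(distances)) return(list(mode = NA_real_, iqr = NA_real_, n = 0L))
  tb <- table(distances)
  mode <- as.numeric(names(tb)[which.max(tb)]) # which.max takes first = smallest
  q <- stats::quantile(distances, c(0.25, 0.75), type = 7, names = FALSE)
  list(mode = mode, iqr = q[2] - q[1], n = length(distances))
}
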