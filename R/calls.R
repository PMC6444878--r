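#' Call positioned nucleosomes from a smoothed occupancy track
#'
#' Summits are local maxima of the smoothed signal with value at or above
#' `min_occupancy`; a plateau of equal values higher than both neighbours
#' counts as one summit at its (left-of-) center base. Retained summits are
#' selected greedily by descending occupancy (ties broken by leftmost
#' coordinate) subject to a minimum summit-to-summit distance. The default
#' separation of 55 bp resolves adjacent nucleosomes whose spacing has
#' collapsed under a positional shift, down to the resolution limit of the
#' default 20-bp smoothing kernel. Each call's footprint is the fixed
#' 147-bp window `summit +/- 73` (clipped at chromosome ends), matching the
#' length of DNA wrapped around the histone octamer. When the supporting
#' fragments are supplied, fuzziness (the sample standard deviation of dyads
#' within the footprint) is attached.
#'
#' @param track a smoothed `OccupancyTrack` (a warning is issued when
#'   `smoothing == 0`).
#' @param min_occupancy minimum summit value (same units as the track).
#' @param min_summit_distance minimum distance between retained summits (bp).
#' @param frags optional `FragmentSet` for fuzziness scoring.
#' @param sample_label label stored on the calls.
#' @return data.frame with columns `chrom`, `summit`, `start`, `end`,
#'   `occupancy`, `fuzziness`, `sample_label`; zero rows when no summit
#'   qualifies.
#' @export
call_nucleosomes <- function(track, min_occupancy = 1,
                             min_summit_distance = 55, frags = NULL,
                             sample_label = "sample") {
  stopifnot(inherits(track, "OccupancyTrack"))
  if (track$smoothing == 0)
    warning("calling nucleosomes on an unsmoothed track")
  out <- list()
  for (cm in names(track$values)) {
    v <- track$values[[cm]]
    n <- length(v)
    if (n < 3) next
    cand <- .plateau_maxima(v)
    cand <- cand[v[cand] >= min_occupancy]
    if (!length(cand)) next
    cand <- cand[order(-v[cand], cand)]
    kept <- integer(0)
    for (i in cand) {
      if (!length(kept) || all(abs(kept - i) >= min_summit_distance))
        kept <- c(kept, i)
    }
    kept <- sort(kept)
    summit <- kept - 1L # 0-based
    calls <- data.frame(chrom = cm, summit = summit,
                        start = pmax(0L, summit - 73L),
                        end = pmin(n, summit + 74L),
                        occupancy = v[kept], fuzziness = NA_real_,
                        sample_label = sample_label,
                        stringsAsFactors = FALSE)
    out[[cm]] <- calls
  }
  if (!length(out))
    return(data.frame(chrom = character(), summit = integer(),
                      start = integer(), end = integer(),
                      occupancy = numeric(), fuzziness = numeric(),
                      sample_label = character(), stringsAsFactors = FALSE))
  calls <- do.call(rbind, out)
  rownames(calls) <- NULL
  if (!is.null(frags))
    calls$fuzziness <- vapply(seq_len(nrow(calls)), function(i)
      call_fuzziness(calls[i, ], frags), numeric(1))
  calls
}

#' Positional fuzziness of one nucleosome call
#'
#' Sample standard deviation (bp) of the dyads of fragments falling within
#' the call's footprint. Undefined (NA) with fewer than two supporting
#' dyads.
#'
#' @param call a single-row call data.frame (`chrom`, `start`, `end`).
#' @param frags a `FragmentSet`.
#' @return fuzziness in bp, or `NA`.
#' @export
call_fuzziness <- function(call, frags) {
  df <- frags$fragments
  d <- dyads(df)
  sel <- df$chrom == call$chrom & d >= call$start & d < call$end
  if (sum(sel) < 2) return(NA_real_)
  stats::sd(d[sel])
}

#' Signed per-base positional-difference track between two conditions
#'
#' At each base, dyad counts are summed over a centered window in each
#' condition, a pseudocount of 1 is added on both sides, and the
#' condition-B count is tested against condition A with the exact
#' conditional test for comparing two Poisson counts (binomial on the B
#' count given the window total, with success probability
#' `totalB / (totalA + totalB)`), two-sided. The score is `-log10(p)` where
#' depth-scaled B exceeds A, `+log10(p)` where A exceeds B, and 0 at equal
#' scaled counts, so `positional_difference(A, B) ==
#' -positional_difference(B, A)` exactly.
#'
#' @param trackA,trackB raw dyad-count `OccupancyTrack`s on the same
#'   chromosomes.
#' @param totalA,totalB total mapped fragment counts (library sizes).
#' @param window centered window width in bp (odd widths are symmetric; an
#'   even width extends one extra base to the left).
#' @return An `OccupancyTrack` with units `"signed_log10_p"`.
#' @export
positional_difference <- function(trackA, trackB,
                                  totalA = trackA$total_count,
                                  totalB = trackB$total_count,
                                  window = 147) {
  stopifnot(inherits(trackA, "OccupancyTrack"),
            inherits(trackB, "OccupancyTrack"), window >= 1)
  if (is.null(totalA) || is.null(totalB) || totalA <= 0 || totalB <= 0)
    stop("totalA and totalB must be positive")
  if (!identical(sort(names(trackA$values)), sort(names(trackB$values))))
    stop("tracks cover different chromosomes")
  pA <- totalA / (totalA + totalB)
  pB <- totalB / (totalA + totalB)
  vals <- list()
  for (cm in names(trackA$values)) {
    a <- trackA$values[[cm]]
    b <- trackB$values[[cm]]
    if (length(a) != length(b))
      stop("tracks have different extents on ", cm)
    wa <- .windowed_sum(a, window) + 1
    wb <- .windowed_sum(b, window) + 1
    ntot <- wa + wb
    # two-sided tails written symmetrically in the two conditions:
    # P(X >= b | X ~ Bin(n, pB)) = P(n - X <= a) with n - X ~ Bin(n, pA),
    # so swapping (A, B) swaps lo and hi bit-exactly
    lo <- stats::pbinom(wb, ntot, pB)
    hi <- stats::pbinom(wa, ntot, pA)
    p <- pmin(1, 2 * pmin(lo, hi))
    # cross-multiplied depth scaling keeps the sign rule exactly antisymmetric
    sgn <- sign(wa * totalB - wb * totalA) # >0: A exceeds scaled B
    vals[[cm]] <- -sgn * log10(p) # B above A => negative score

  }
  occupancy_track(vals, units = "signed_log10_p", mode = trackA$mode,
                  smoothing = 0)
}

# Local maxima of a numeric vector, plateau-aware: a run of equal values
# strictly higher than both flanking values is one maximum at its center
# base (left of center for even runs). Returns 1-based indices.
.plateau_maxima <- function(v) {
  n <- length(v)
  if (n < 3) return(integer(0))
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  k <- length(r$values)
  if (k < 3) return(integer(0))
  mid <- 2:(k - 1)
  is_max <- r$values[mid] > r$values[mid - 1] & r$values[mid] > r$values[mid + 1]
  runs <- mid[is_max]
  as.integer(floor((starts[runs] + ends[runs]) / 2))
}

# Centered moving window sum with edges clipped to the vector.
.windowed_sum <- function(x, window) {
  n <- length(x)
  half_r <- (window - 1) %/% 2
  half_l <- window - 1 - half_r
  cs <- c(0, cumsum(x))
  i <- seq_len(n)
  lo <- pmax(i - half_l, 1L)
  hi <- pmin(i + half_r, n)
  cs[hi + 1] - cs[lo]
}
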