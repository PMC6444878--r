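#' Construct an OccupancyTrack
#'
#' A per-base signal over one or more chromosomes, with base 0 at vector
#' index 1. Units are raw counts or RPBM (reads per base per million mapped
#' reads).
#'
#' @param values named list of per-chromosome numeric vectors.
#' @param units `"raw"` or `"RPBM"`.
#' @param mode `"dyad"` or `"coverage"`.
#' @param smoothing smoothing bandwidth in bp (0 = unsmoothed).
#' @param total_count optional total mapped fragments backing the track.
#' @return An object of class `OccupancyTrack`.
#' @export
occupancy_track <- function(values, units = "raw", mode = "dyad",
                            smoothing = 0, total_count = NULL) {
  stopifnot(is.list(values), !is.null(names(values)))
  structure(list(values = values, units = units, mode = mode,
                 smoothing = smoothing, total_count = total_count),
            class = "OccupancyTrack")
}

#' @export
print.OccupancyTrack <- function(x, ...) {
  cat("OccupancyTrack [", x$units, ", ", x$mode, ", bw=", x$smoothing, "]: ",
      length(x$values), " chrom(s), ",
      format(sum(vapply(x$values, length, 0))), " bp\n", sep = "")
  invisible(x)
}

#' Per-base dyad or coverage density from fragments
#'
#' In dyad mode each fragment adds 1 at its dyad base, so the genome-wide
#' integral equals the fragment count; in coverage mode each fragment adds 1
#' over its footprint `[start, end)`.
#'
#' @param frags a `FragmentSet`.
#' @param mode `"dyad"` (default) or `"coverage"`.
#' @param chrom_lengths optional named vector of chromosome lengths;
#'   defaults to the largest fragment end per chromosome.
#' @return A raw-unit `OccupancyTrack`.
#' @export
dyad_density <- function(frags, mode = c("dyad", "coverage"),
                         chrom_lengths = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(frags, "FragmentSet"))
  df <- frags$fragments
  chroms <- if (!is.null(chrom_lengths)) names(chrom_lengths) else unique(df$chrom)
  vals <- list()
  for (cm in chroms) {
    sub <- df[df$chrom == cm, , drop = FALSE]
    len <- if (!is.null(chrom_lengths)) as.integer(chrom_lengths[[cm]])
           else if (nrow(sub)) max(sub$end) else 0L
    v <- numeric(len)
    if (nrow(sub)) {
      if (mode == "dyad") {
        d <- dyads(sub)
        v <- tabulate(d + 1L, nbins = len)
      } else {
        # difference-array trick: +1 at start, -1 at end, then cumsum
        delta <- numeric(len + 1L)
        tb <- tabulate(sub$start + 1L, nbins = len + 1L)
        delta <- delta + tb
        tb <- tabulate(pmin(sub$end, len) + 1L, nbins = len + 1L)
        delta <- delta - tb
        v <- cumsum(delta)[seq_len(len)]
      }
    }
    vals[[cm]] <- as.numeric(v)
  }
  occupancy_track(vals, units = "raw", mode = mode,
                  total_count = frags$total_count)
}

#' Normalize a raw track to RPBM
#'
#' RPBM (reads per base per million mapped reads) multiplies each per-base
#' value by `1e6 / total_count`, making tracks comparable across sequencing
#' depths: duplicating every fragment leaves RPBM unchanged.
#'
#' @param track a raw-unit `OccupancyTrack`.
#' @param total_count total mapped fragments; defaults to the count stored on
#'   the track.
#' @return An RPBM `OccupancyTrack`.
#' @export
rpbm_normalize <- function(track, total_count = track$total_count) {
  stopifnot(inherits(track, "OccupancyTrack"))
  if (is.null(total_count) || total_count <= 0)
    stop("total_count must be positive for RPBM normalization")
  if (track$units == "RPBM") stop("track is already RPBM-normalized")
  f <- 1e6 / total_count
  track$values <- lapply(track$values, function(v) v * f)
  track$units <- "RPBM"
  track$total_count <- total_count
  track
}

#' Smooth an occupancy track with a unit-mass kernel
#'
#' Discrete convolution with a normalized gaussian (sd = bandwidth, truncated
#' at 4 sd) or triangular (half-width = bandwidth) kernel. Edges are handled
#' by reflection so total signal is conserved. Bandwidth 0 returns the input
#' unchanged.
#'
#' @param track an `OccupancyTrack`.
#' @param bandwidth kernel scale in bp.
#' @param kernel `"gaussian"` or `"triangular"`.
#' @return A smoothed `OccupancyTrack`.
#' @export
smooth_track <- function(track, bandwidth = 20,
                         kernel = c("gaussian", "triangular")) {
  kernel <- match.arg(kernel)
  stopifnot(inherits(track, "OccupancyTrack"))
  if (bandwidth < 0) stop("bandwidth must be non-negative")
  if (bandwidth == 0) return(track)
  if (kernel == "gaussian") {
    half <- ceiling(4 * bandwidth)
    k <- stats::dnorm(seq(-half, half), sd = bandwidth)
  } else {
    half <- ceiling(bandwidth)
    k <- pmax(0, 1 - abs(seq(-half, half)) / bandwidth)
  }
  k <- k / sum(k)
  track$values <- lapply(track$values, function(v) {
    n <- length(v)
    if (n == 0) return(v)
    h <- min(half, n - 1L)
    kk <- if (h < half) { # short chromosome: re-truncate and renormalize
      kt <- k[(half - h + 1):(half + h + 1)]; kt / sum(kt)
    } else k
    pad <- c(rev(v[seq_len(h)]), v, rev(v[(n - h + 1):n]))
    sm <- stats::filter(pad, kk, method = "convolution", sides = 2)
    as.numeric(sm[(h + 1):(h + n)])
  })
  track$smoothing <- bandwidth
  track
}

#' Strand-aware average profile of a track around anchors
#'
#' For each offset in `-flank..flank`, averages the track value at
#' `position + offset` for plus-strand anchors and `position - offset` for
#' minus-strand anchors. Anchors whose window leaves the chromosome (or whose
#' chromosome is absent from the track) are dropped and counted.
#'
#' @param track an `OccupancyTrack`.
#' @param anchors anchor data.frame from [read_anchors()].
#' @param flank half-window in bp.
#' @return A `Profile1D` list: `offsets`, `mean_density`, `n_anchors`,
#'   `n_dropped`, `units`.
#' @export
profile_1d <- function(track, anchors, flank = 1000) {
  stopifnot(inherits(track, "OccupancyTrack"), flank > 0, nrow(anchors) > 0)
  offsets <- seq.int(-flank, flank)
  acc <- numeric(length(offsets))
  used <- 0L
  for (i in seq_len(nrow(anchors))) {
    cm <- anchors$chrom[i]
    if (!cm %in% names(track$values)) next
    v <- track$values[[cm]]
    p <- anchors$position[i]
    if (p - flank < 0 || p + flank >= length(v)) next
    w <- v[(p - flank + 1):(p + flank + 1)]
    if (anchors$strand[i] == "-") w <- rev(w)
    acc <- acc + w
    used <- used + 1L
  }
  if (used == 0L) stop("no usable anchors: all windows leave the track")
  structure(list(offsets = offsets, mean_density = acc / used,
                 n_anchors = used, n_dropped = nrow(anchors) - used,
                 units = track$units),
            class = "Profile1D")
}

#' Per-anchor signal heatmap ordered by a sort key
#'
#' One row per retained anchor (strand-oriented window, as in
#' [profile_1d()]), ordered by ascending `sort_key` with ties broken by
#' anchor name. Row means reproduce the average profile over the same
#' anchors.
#'
#' @param track an `OccupancyTrack`.
#' @param anchors anchor data.frame.
#' @param flank half-window in bp.
#' @param sort_key numeric vector named by anchor name (anchors with a
#'   missing key are dropped with a warning).
#' @return numeric matrix with `offsets` attribute; rownames are anchor
#'   names.
#' @export
anchor_heatmap <- function(track, anchors, flank, sort_key) {
  stopifnot(inherits(track, "OccupancyTrack"))
  key <- sort_key[anchors$name]
  miss <- is.na(key)
  if (any(miss)) {
    warning(sum(miss), " anchor(s) dropped: missing sort_key")
    anchors <- anchors[!miss, , drop = FALSE]
    key <- key[!miss]
  }
  offsets <- seq.int(-flank, flank)
  rows <- list()
  keys <- numeric(0)
  for (i in seq_len(nrow(anchors))) {
    cm <- anchors$chrom[i]
    if (!cm %in% names(track$values)) next
    v <- track$values[[cm]]
    p <- anchors$position[i]
    if (p - flank < 0 || p + flank >= length(v)) next
    w <- v[(p - flank + 1):(p + flank + 1)]
    if (anchors$strand[i] == "-") w <- rev(w)
    rows[[anchors$name[i]]] <- w
    keys[anchors$name[i]] <- key[i]
  }
  if (!length(rows)) stop("no usable anchors")
  ord <- order(keys, names(rows))
  m <- do.call(rbind, rows[ord])
  attr(m, "offsets") <- offsets
  m
}

#' 2D occupancy: fragment length by position relative to anchors
#'
#' Builds the matrix of mean dyad counts per (fragment-length bin,
#' strand-oriented offset) across anchors, plus the marginal profile over
#' lengths. Column sums over length bins reproduce the 1D dyad profile of
#' the same length-restricted fragments on the same anchors.
#'
#' @param frags a `FragmentSet`.
#' @param anchors anchor data.frame.
#' @param flank half-window in bp.
#' @param length_range inclusive fragment-length window, within [50, 300].
#' @param length_bin bin width in bp (>= 1).
#' @param chrom_lengths optional named chromosome lengths (defaults to
#'   largest fragment end per chromosome) used for the anchor edge rule.
#' @return An `Occupancy2D` list: `offsets`, `length_bins` (bin start
#'   coordinates), `matrix` (length bin x offset), `marginal_profile`,
#'   `n_anchors`.
#' @export
occupancy_2d <- function(frags, anchors, flank = 1000,
                         length_range = c(100, 250), length_bin = 1,
                         chrom_lengths = NULL) {
  stopifnot(inherits(frags, "FragmentSet"), length_bin >= 1)
  if (length_range[1] > length_range[2]) stop("empty length_range")
  if (length_range[1] < 50 || length_range[2] > 300)
    stop("length_range must lie within [50, 300]")
  df <- frags$fragments
  keep <- df$length >= length_range[1] & df$length <= length_range[2]
  df <- df[keep, , drop = FALSE]
  d <- if (nrow(df)) dyads(df) else integer(0)
  if (is.null(chrom_lengths)) {
    all_df <- frags$fragments
    chrom_lengths <- tapply(all_df$end, all_df$chrom, max)
  }
  bin_starts <- seq.int(length_range[1], length_range[2], by = length_bin)
  bin_of <- function(L) pmin(findInterval(L, bin_starts), length(bin_starts))
  offsets <- seq.int(-flank, flank)
  m <- matrix(0, nrow = length(bin_starts), ncol = length(offsets),
              dimnames = list(bin_starts, offsets))
  used <- 0L
  for (i in seq_len(nrow(anchors))) {
    cm <- anchors$chrom[i]
    clen <- chrom_lengths[[cm]]
    if (is.null(clen) || is.na(clen)) next
    p <- anchors$position[i]
    if (p - flank < 0 || p + flank >= clen) next
    used <- used + 1L
    j <- which(df$chrom == cm & d >= p - flank & d <= p + flank)
    if (!length(j)) next
    off <- d[j] - p
    if (anchors$strand[i] == "-") off <- -off
    rows <- bin_of(df$length[j])
    cols <- off + flank + 1L
    for (t in seq_along(j)) m[rows[t], cols[t]] <- m[rows[t], cols[t]] + 1
  }
  if (used == 0L) stop("no usable anchors")
  m <- m / used
  structure(list(offsets = offsets, length_bins = bin_starts, matrix = m,
                 marginal_profile = colSums(m), n_anchors = used),
            class = "Occupancy2D")
}

#' Fragment-length histogram and density
#'
#' @param frags a `FragmentSet`.
#' @return data.frame with `length`, `count` and `density` (density sums
#'   to 1).
#' @export
fragment_length_density <- function(frags) {
  stopifnot(inherits(frags, "FragmentSet"))
  if (nrow(frags$fragments) == 0) stop("no fragments")
  tb <- table(frags$fragments$length)
  data.frame(length = as.integer(names(tb)),
             count = as.integer(tb),
             density = as.numeric(tb) / sum(tb))
}

#' Write a 1D profile as TSV
#' @param profile a `Profile1D`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  write.table(data.frame(offset = profile$offsets,
                         mean_density = profile$mean_density),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
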