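#' Dinucleotide composition profile around nucleosome dyads
#'
#' At each offset o in `-flank..flank`, computes the fraction of sites whose
#' dinucleotide starting at `dyad + o` (in gene/strand orientation;
#' minus-strand sites are reverse-complemented) belongs to the W|W
#' (AA/AT/TA/TT) and S|S (GC/CG by default) sets. Sites whose window leaves
#' the chromosome are dropped and counted; dinucleotides containing
#' ambiguity codes are excluded from the denominator at that offset.
#'
#' @param genome named character vector from [read_genome()].
#' @param sites data.frame with `chrom`, `position` (dyad, 0-based),
#'   `strand`.
#' @param flank half-window in bp.
#' @param ss_set strong (G+C) dinucleotide set; `c("GC","CG")` as printed in
#'   the dinucleotide convention, or all four S|S steps.
#' @param ww_set weak (A+T) dinucleotide set.
#' @return A `CompositionProfile` list: `offsets`, `ww_freq`, `ss_freq`,
#'   `n_sites`, `n_dropped`.
#' @export
dinucleotide_profile <- function(genome, sites, flank = 100,
                                 ss_set = c("GC", "CG"),
                                 ww_set = c("AA", "AT", "TA", "TT")) {
  if (nrow(sites) == 0) stop("empty dyad set")
  wins <- .oriented_windows(genome, sites, left = flank + 1L, right = flank + 1L)
  if (!length(wins$seq)) stop("no usable dyad windows")
  chars <- do.call(rbind, strsplit(wins$seq, ""))
  offsets <- seq.int(-flank, flank)
  ww <- ss <- numeric(length(offsets))
  for (j in seq_along(offsets)) {
    di <- paste0(chars[, j + 1L], chars[, j + 2L])
    ok <- grepl("^[ACGT]{2}$", di)
    denom <- sum(ok)
    ww[j] <- if (denom) sum(di[ok] %in% ww_set) / denom else NA_real_
    ss[j] <- if (denom) sum(di[ok] %in% ss_set) / denom else NA_real_
  }
  structure(list(offsets = offsets, ww_freq = ww, ss_freq = ss,
                 n_sites = length(wins$seq), n_dropped = wins$n_dropped),
            class = "CompositionProfile")
}

#' Positional k-mer count matrix around summits
#'
#' Counts every observed k-mer by the window bin containing its
#' strand-oriented start offset; bins of width `window` tile
#' `[-flank, +flank)`. Each row (k-mer) is then converted to per-bin
#' frequencies and z-scored across bins.
#'
#' @param genome named character vector.
#' @param summits data.frame with `chrom`, `position`, `strand`.
#' @param k k-mer length.
#' @param window bin width in bp; `flank` must be a multiple of it.
#' @param flank half-range in bp (130 by convention; 125 also in use).
#' @return A `KmerPositionMatrix` list: `counts` (k-mer x bin integer
#'   matrix), `zscore`, `bin_starts`, `k`, `window`, `flank`, `n_sites`.
#' @export
kmer_positional_counts <- function(genome, summits, k = 6, window = 10,
                                   flank = 130) {
  if (flank %% window != 0) stop("flank must be a multiple of window")
  wins <- .oriented_windows(genome, summits, left = flank,
                            right = flank + k - 1L)
  bin_starts <- seq.int(-flank, flank - window, by = window)
  bin_labels <- sprintf("[%d,%d)", bin_starts, bin_starts + window)
  counts <- list()
  starts <- seq.int(-flank, flank - 1L)
  bin_idx <- (starts + flank) %/% window + 1L
  for (w in wins$seq) {
    for (t in seq_along(starts)) {
      km <- substr(w, t, t + k - 1L)
      if (!grepl("^[ACGT]+$", km) || nchar(km) < k) next
      key <- km
      if (is.null(counts[[key]])) counts[[key]] <- integer(length(bin_starts))
      counts[[key]][bin_idx[t]] <- counts[[key]][bin_idx[t]] + 1L
    }
  }
  if (!length(counts)) {
    m <- matrix(integer(0), nrow = 0, ncol = length(bin_starts),
                dimnames = list(NULL, bin_labels))
    z <- matrix(numeric(0), nrow = 0, ncol = length(bin_starts),
                dimnames = list(NULL, bin_labels))
  } else {
    m <- do.call(rbind, counts)
    dimnames(m) <- list(names(counts), bin_labels)
    m <- m[order(rownames(m)), , drop = FALSE]
    freq <- m / pmax(rowSums(m), 1L)
    z <- t(apply(freq, 1, function(r) {
      s <- stats::sd(r)
      if (is.na(s) || s == 0) rep(0, length(r)) else (r - mean(r)) / s
    }))
    dimnames(z) <- dimnames(m)
  }
  structure(list(counts = m, zscore = z, bin_starts = bin_starts,
                 k = k, window = window, flank = flank,
                 n_sites = length(wins$seq), n_dropped = wins$n_dropped),
            class = "KmerPositionMatrix")
}

#' Annotate positions as promoter, gene body or intergenic
#'
#' The promoter is the gene-oriented window from `promoter_upstream` bp
#' upstream of the TSS to `promoter_downstream` bp downstream (1 kb / 100 bp
#' by convention); the gene body is the remainder of [TSS, TES]. Promoter
#' wins on overlap.
#'
#' @param positions data.frame with `chrom`, `position`.
#' @param genes gene data.frame with `gene_id`, `chrom`, `strand`, `tss`,
#'   `tes`.
#' @param promoter_upstream,promoter_downstream promoter extent in bp.
#' @return character vector: `"promoter"`, `"gene_body"` or `"intergenic"`.
#' @export
annotate_genic <- function(positions, genes, promoter_upstream = 1000,
                           promoter_downstream = 100) {
  out <- rep("intergenic", nrow(positions))
  for (i in seq_len(nrow(genes))) {
    dirn <- if (genes$strand[i] == "+") 1L else -1L
    tss <- genes$tss[i]
    prom <- sort(c(tss - dirn * promoter_upstream,
                   tss + dirn * promoter_downstream))
    body <- sort(c(tss, genes$tes[i]))
    on_chrom <- positions$chrom == genes$chrom[i]
    p <- positions$position
    in_body <- on_chrom & p >= body[1] & p <= body[2]
    out[in_body & out == "intergenic"] <- "gene_body"
    in_prom <- on_chrom & p >= prom[1] & p <= prom[2]
    out[in_prom] <- "promoter" # promoter wins on overlap
  }
  out
}

# Strand-oriented sequence windows: for each site, the oriented sequence
# from `left` bp upstream (5') of the position to `right` bp downstream,
# i.e. length left + right + 1, with index left + 1 at the site. Sites whose
# window leaves the chromosome (or whose chromosome is absent) are dropped.
.oriented_windows <- function(genome, sites, left, right) {
  seqs <- character(0)
  dropped <- 0L
  for (i in seq_len(nrow(sites))) {
    cm <- sites$chrom[i]
    if (!cm %in% names(genome)) { dropped <- dropped + 1L; next }
    p <- sites$position[i]
    clen <- nchar(genome[[cm]])
    minus <- identical(sites$strand[i], "-")
    lo <- if (minus) p - right else p - left
    hi <- if (minus) p + left else p + right
    if (lo < 0 || hi >= clen) { dropped <- dropped + 1L; next }
    w <- substr(genome[[cm]], lo + 1L, hi + 1L)
    if (minus)
      w <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(w)))
    seqs <- c(seqs, w)
  }
  list(seq = seqs, n_dropped = dropped)
}

#' Write a composition profile as TSV
#' @param profile a `CompositionProfile`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_composition_profile <- function(profile, path) {
  write.table(data.frame(offset = profile$offsets, ww_freq = profile$ww_freq,
                         ss_freq = profile$ss_freq),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
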