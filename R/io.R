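#' Read anchor points from BED6
#'
#' Anchors are single-bp reference points for profile computation. For the
#' TSS class the point is the annotated start site: the `start` field on the
#' plus strand, `end - 1` on the minus strand (both 0-based). Other classes
#' (DHS, CTCF, TF, other) use the interval midpoint and default to the plus
#' strand when no strand is annotated.
#'
#' @param path BED6 file (BED3 accepted for non-TSS classes).
#' @param anchor_class one of `"TSS"`, `"DHS"`, `"CTCF"`, `"TF"`, `"other"`.
#' @return data.frame with columns `chrom`, `position`, `strand`, `name`,
#'   `class`.
#' @export
read_anchors <- function(path, anchor_class = c("TSS", "DHS", "CTCF", "TF", "other")) {
  anchor_class <- match.arg(anchor_class)
  lines <- .read_body_lines(path)
  if (length(lines$text) == 0L) stop("empty anchor file: ", path)
  fields <- strsplit(lines$text, "[ \t]+")
  nf <- lengths(fields)
  bad <- which(nf < 3L)
  if (length(bad))
    stop("malformed BED line ", lines$lineno[bad[1]], " in ", path)
  chrom <- vapply(fields, `[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad))
    stop("malformed coordinates at line ", lines$lineno[bad[1]], " in ", path)
  if (any(start < 0)) stop("negative coordinates in ", path)
  name <- ifelse(nf >= 4L, vapply(fields, function(f) f[4], ""),
                 paste0("anchor", seq_along(fields)))
  strand <- ifelse(nf >= 6L, vapply(fields, function(f) f[6], ""), ".")
  if (anchor_class == "TSS") {
    if (any(!strand %in% c("+", "-")))
      stop("TSS anchors require a +/- strand column in ", path)
    position <- ifelse(strand == "+", start, end - 1)
  } else {
    strand[!strand %in% c("+", "-")] <- "+"
    position <- floor((start + end) / 2)
  }
  data.frame(chrom = chrom, position = as.integer(position), strand = strand,
             name = name, class = anchor_class, stringsAsFactors = FALSE)
}

#' Read a genome from FASTA
#'
#' @param path FASTA file.
#' @return named character vector of uppercase sequences (ambiguity codes
#'   retained), one element per chromosome.
#' @export
read_genome <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  nm <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(nm))
    stop("duplicate chromosome names in ", path, ": ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  out <- toupper(as.character(seqs))
  names(out) <- nm
  out
}

#' Write a genome to FASTA
#' @param genome named character vector of sequences.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome), path)
  invisible(path)
}

#' Write an occupancy track as bedGraph
#'
#' Consecutive equal values are run-length merged; coordinates are 0-based
#' half-open. Values are printed at full double precision so a read-back
#' reproduces them exactly.
#'
#' @param track an `OccupancyTrack`.
#' @param path output file.
#' @param keep_zero if `FALSE` (default) zero runs are omitted from the body;
#'   if `TRUE` they are written as intervals.
#' @return `path`, invisibly.
#' @export
write_track <- function(track, path, keep_zero = FALSE) {
  stopifnot(inherits(track, "OccupancyTrack"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# nucshift bedGraph units=%s mode=%s smoothing=%s",
                     track$units, track$mode, format(track$smoothing)), con)
  for (chrom in names(track$values)) {
    v <- track$values[[chrom]]
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- if (keep_zero) seq_along(r$values) else which(r$values != 0)
    if (length(keep))
      writeLines(sprintf("%s\t%d\t%d\t%.17g", chrom, starts[keep], ends[keep],
                         r$values[keep]), con)
  }
  invisible(path)
}

#' Read a bedGraph track written by [write_track()]
#'
#' @param path bedGraph file.
#' @param chrom_lengths optional named vector of chromosome lengths; defaults
#'   to the largest end coordinate seen per chromosome.
#' @return An `OccupancyTrack` (raw units unless the file header records
#'   otherwise).
#' @export
read_track <- function(path, chrom_lengths = NULL) {
  raw <- readLines(path, warn = FALSE)
  units <- "raw"; mode <- "dyad"; smoothing <- 0
  hdr <- grep("^# nucshift bedGraph", raw, value = TRUE)
  if (length(hdr)) {
    units <- sub(".*units=(\\S+).*", "\\1", hdr[1])
    mode <- sub(".*mode=(\\S+).*", "\\1", hdr[1])
    smoothing <- as.numeric(sub(".*smoothing=(\\S+).*", "\\1", hdr[1]))
  }
  body <- raw[nzchar(raw) & !grepl("^(#|track|browser)", raw)]
  vals <- list()
  if (length(body)) {
    fields <- strsplit(body, "\t")
    chrom <- vapply(fields, `[`, "", 1L)
    start <- as.integer(vapply(fields, `[`, "", 2L))
    end <- as.integer(vapply(fields, `[`, "", 3L))
    value <- as.numeric(vapply(fields, `[`, "", 4L))
    for (cm in unique(chrom)) {
      i <- chrom == cm
      len <- if (!is.null(chrom_lengths) && cm %in% names(chrom_lengths))
        chrom_lengths[[cm]] else max(end[i])
      v <- numeric(len)
      for (j in which(i)) v[(start[j] + 1):end[j]] <- value[j]
      vals[[cm]] <- v
    }
  }
  occupancy_track(vals, units = units, mode = mode, smoothing = smoothing)
}

#' Write nucleosome calls as TSV
#' @param calls data.frame of calls (see [call_nucleosomes()]).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_nucleosome_calls <- function(calls, path) {
  cols <- c("chrom", "summit", "start", "end", "occupancy", "fuzziness",
            "sample_label")
  stopifnot(all(cols %in% names(calls)))
  write.table(calls[, cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read nucleosome calls from TSV
#' @param path TSV written by [write_nucleosome_calls()].
#' @return data.frame of calls.
#' @export
read_nucleosome_calls <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  cols <- c("chrom", "summit", "start", "end", "occupancy", "fuzziness",
            "sample_label")
  if (!all(cols %in% names(df)))
    stop("nucleosome call table ", path, " is missing columns: ",
         paste(setdiff(cols, names(df)), collapse = ", "))
  bad <- which(!is.finite(df$summit) | df$summit < df$start | df$summit >= df$end)
  if (length(bad))
    stop("summit outside [start, end) at line ", bad[1] + 1L, " in ", path)
  df
}

#' Read a differential-expression table
#'
#' Assigns each gene an up/down/unchanged status using fold-change and FDR
#' thresholds (defaults 1.5-fold and FDR < 0.001, the conventional cutoffs
#' for edgeR-style DE calls between the two conditions).
#'
#' @param path TSV with header columns `gene_id`, `log2fc`, `fdr` (extra
#'   columns such as `rpkm` are carried through).
#' @param fc_threshold linear fold-change threshold (> 1).
#' @param fdr_threshold FDR cutoff in (0, 1].
#' @return data.frame with an added `status` column.
#' @export
read_de_table <- function(path, fc_threshold = 1.5, fdr_threshold = 0.001) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "log2fc", "fdr")
  if (!all(need %in% names(df)))
    stop("DE table ", path, " is missing columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  if (any(df$fdr < 0 | df$fdr > 1, na.rm = TRUE))
    stop("fdr values outside [0, 1] in ", path)
  df$status <- de_status(df$log2fc, df$fdr, fc_threshold, fdr_threshold)
  df
}

#' Classify log2 fold-changes into up/down/unchanged
#' @param log2fc log2 fold-change values.
#' @param fdr false-discovery-rate values in [0, 1].
#' @param fc_threshold linear fold-change threshold.
#' @param fdr_threshold FDR cutoff.
#' @return character vector of `"up"`, `"down"`, `"unchanged"`.
#' @export
de_status <- function(log2fc, fdr, fc_threshold = 1.5, fdr_threshold = 0.001) {
  lt <- log2(fc_threshold)
  ifelse(fdr < fdr_threshold & log2fc >= lt, "up",
         ifelse(fdr < fdr_threshold & log2fc <= -lt, "down", "unchanged"))
}
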