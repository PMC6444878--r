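#' Construct a FragmentSet
#'
#' A FragmentSet holds MNase-protected fragments for one sample together with
#' the total mapped fragment count used as the depth-normalization
#' denominator. The total is kept separate from the retained fragments so that
#' RPBM values stay comparable across length-filter settings.
#'
#' @param fragments data.frame with columns `chrom`, `start`, `end`
#'   (0-based half-open) and optionally `length` (recomputed if absent).
#' @param total_count total mapped fragments; must be at least the number of
#'   retained fragments and positive for any normalization.
#' @param sample_label label for the sample/condition.
#' @return An object of class `FragmentSet`.
#' @export
fragment_set <- function(fragments, total_count = nrow(fragments),
                         sample_label = "sample") {
  stopifnot(is.data.frame(fragments),
            all(c("chrom", "start", "end") %in% names(fragments)))
  if (nrow(fragments) > 0 && any(fragments$end <= fragments$start))
    stop("fragment end must be greater than start")
  fragments$length <- fragments$end - fragments$start
  if (total_count < nrow(fragments))
    stop("total_count (", total_count, ") is smaller than the number of fragments (",
         nrow(fragments), ")")
  structure(list(sample_label = sample_label,
                 fragments = fragments[, c("chrom", "start", "end", "length")],
                 total_count = as.numeric(total_count)),
            class = "FragmentSet")
}

#' @export
print.FragmentSet <- function(x, ...) {
  cat("FragmentSet '", x$sample_label, "': ", nrow(x$fragments),
      " fragments (total mapped: ", format(x$total_count), ")\n", sep = "")
  invisible(x)
}

#' Fragment dyad positions
#'
#' The dyad is the center base of the protected fragment,
#' `floor((start + end - 1) / 2)`: the midpoint of the inclusive span,
#' deterministic (rounded down) for even lengths.
#'
#' @param frags a `FragmentSet` or a data.frame with `start`/`end`.
#' @return integer vector of 0-based dyad positions.
#' @export
dyads <- function(frags) {
  df <- if (inherits(frags, "FragmentSet")) frags$fragments else frags
  as.integer(floor((df$start + df$end - 1) / 2))
}

#' Read MNase-Seq fragments from BED or BEDPE
#'
#' BEDPE mates are merged to the outer fragment span. `total_count` records
#' the number of parsed records before any length filtering, so it is
#' invariant to `min_len`/`max_len`.
#'
#' @param path BED3+ (one interval per fragment) or 10-column BEDPE file.
#' @param min_len,max_len optional inclusive fragment-length limits in bp.
#' @param format `"auto"` (default), `"bed"` or `"bedpe"`.
#' @param dedup drop exact-coordinate duplicate fragments (default off; the
#'   upstream mapping is assumed to have removed redundant reads).
#' @param sample_label label stored on the returned set.
#' @return A `FragmentSet`.
#' @export
read_fragments <- function(path, min_len = NULL, max_len = NULL,
                           format = c("auto", "bed", "bedpe"),
                           dedup = FALSE, sample_label = NULL) {
  format <- match.arg(format)
  lines <- .read_body_lines(path)
  if (length(lines$text) == 0L) stop("empty fragment file: ", path)
  fields <- strsplit(lines$text, "[ \t]+")
  nf <- lengths(fields)
  if (format == "auto") {
    f1 <- fields[[1]]
    is_pe <- length(f1) >= 6 &&
      !is.na(suppressWarnings(as.numeric(f1[5]))) &&
      !is.na(suppressWarnings(as.numeric(f1[6]))) &&
      is.na(suppressWarnings(as.numeric(f1[4])))
    format <- if (is_pe) "bedpe" else "bed"
  }
  need <- if (format == "bedpe") 6L else 3L
  bad <- which(nf < need)
  if (length(bad))
    stop("malformed ", format, " line ", lines$lineno[bad[1]], " in ", path,
         ": expected at least ", need, " fields")
  if (format == "bedpe") {
    chrom <- vapply(fields, `[`, "", 1L)
    chrom2 <- vapply(fields, `[`, "", 4L)
    s1 <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2L)))
    e1 <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 3L)))
    s2 <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 5L)))
    e2 <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 6L)))
    bad <- which(is.na(s1) | is.na(e1) | is.na(s2) | is.na(e2))
    if (length(bad))
      stop("malformed coordinates at line ", lines$lineno[bad[1]], " in ", path)
    bad <- which(chrom != chrom2)
    if (length(bad))
      stop("BEDPE mates on different chromosomes at line ", lines$lineno[bad[1]])
    start <- pmin(s1, s2)
    end <- pmax(e1, e2)
  } else {
    chrom <- vapply(fields, `[`, "", 1L)
    start <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2L)))
    end <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 3L)))
    bad <- which(is.na(start) | is.na(end))
    if (length(bad))
      stop("malformed coordinates at line ", lines$lineno[bad[1]], " in ", path)
  }
  bad <- which(start >= end)
  if (length(bad))
    stop("start >= end at line ", lines$lineno[bad[1]], " in ", path)
  df <- data.frame(chrom = chrom, start = start, end = end,
                   length = end - start, stringsAsFactors = FALSE)
  total <- nrow(df)
  if (dedup)
    df <- df[!duplicated(df[, c("chrom", "start", "end")]), , drop = FALSE]
  if (!is.null(min_len)) df <- df[df$length >= min_len, , drop = FALSE]
  if (!is.null(max_len)) df <- df[df$length <= max_len, , drop = FALSE]
  rownames(df) <- NULL
  if (is.null(sample_label))
    sample_label <- sub("\\.(bed|bedpe)(\\.gz)?$", "", basename(path))
  fragment_set(df, total_count = total, sample_label = sample_label)
}

#' Restrict a FragmentSet to canonical nucleosome-length fragments
#'
#' Fragments of 140-180 bp are treated as canonical mononucleosomes by
#' default. The normalization denominator (`total_count`) is preserved from
#' the input set.
#'
#' @param frags a `FragmentSet`.
#' @param lo,hi inclusive length window in bp.
#' @return A `FragmentSet` with only canonical-length fragments.
#' @export
filter_canonical <- function(frags, lo = 140, hi = 180) {
  stopifnot(inherits(frags, "FragmentSet"))
  if (lo > hi) stop("lo must not exceed hi")
  keep <- frags$fragments$length >= lo & frags$fragments$length <= hi
  out <- frags
  out$fragments <- frags$fragments[keep, , drop = FALSE]
  rownames(out$fragments) <- NULL
  out
}

#' Write fragments as BED3
#' @param frags a `FragmentSet`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fragments_bed <- function(frags, path) {
  df <- frags$fragments
  write.table(df[, c("chrom", "start", "end")], path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# Non-empty, non-comment lines with their original line numbers.
.read_body_lines <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(raw)) &
                  !grepl("^(#|track|browser)", trimws(raw)))
  list(text = raw[keep], lineno = keep)
}
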