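#' Simulate a genome with phased nucleosome arrays
#'
#' Builds a single synthetic chromosome carrying `n_genes` non-overlapping
#' genes with random strand, each with the canonical promoter architecture:
#' a nucleosome-depleted region (NDR) upstream of the TSS flanked by the -1
#' and +1 nucleosomes, and phased arrays at fixed center-to-center spacing on
#' both sides. Ground-truth dyads are recorded per condition (both conditions
#' start identical; see [program_shifts()]).
#'
#' Roles are integers relative to the TSS in gene orientation: +1 is the
#' first nucleosome downstream (dyad at `tss + ndr_offset`), +2 the next at
#' `+ spacing`, and so on; -1 is the first upstream (dyad at
#' `+1 dyad - ndr_width`), with further upstream nucleosomes at `- spacing`
#' steps. The NDR is the dyad-free interval between -1 and +1.
#'
#' Base composition is i.i.d. at `gc_fraction`; if `nuc_gc_fraction` differs,
#' bases under the 147-bp footprints of reference-condition dyads are
#' resampled at that G+C level, giving the sequence-composition stage a
#' recoverable signal.
#'
#' @param n_genes number of genes.
#' @param chrom_len chromosome length in bp.
#' @param gc_fraction background G+C fraction in [0, 1].
#' @param ndr_width NDR width in bp (distance between -1 and +1 dyads).
#' @param spacing nucleosome center-to-center spacing in bp (> 147).
#' @param n_nucs_per_side nucleosomes per side of the NDR (roles 1..n and
#'   -1..-n).
#' @param ndr_offset +1 dyad distance downstream of the TSS in bp.
#' @param nuc_gc_fraction G+C fraction under nucleosome footprints (default:
#'   same as background).
#' @param chrom chromosome name.
#' @param seed integer seed; the model is reproducible given the seed.
#' @return A `GenomeModel` list: `sequence`, `chrom_len`, `genes`
#'   (data.frame), `truth` (data.frame: condition, gene_id, role, dyad,
#'   delta, direction), plus the layout parameters and seed.
#' @export
simulate_genome <- function(n_genes, chrom_len, gc_fraction = 0.5,
                            ndr_width = 150, spacing = 190,
                            n_nucs_per_side = 3, ndr_offset = 100,
                            nuc_gc_fraction = gc_fraction,
                            chrom = "chrS", seed = 1) {
  stopifnot(n_genes >= 1, spacing > 147)
  set.seed(seed)
  # span of one gene's array in bp, plus breathing room between genes
  half_span <- ndr_offset + ndr_width + n_nucs_per_side * spacing + 200
  slot <- floor(chrom_len / n_genes)
  if (slot < 2 * half_span)
    stop("infeasible packing: ", n_genes, " genes need chrom_len >= ",
         2 * half_span * n_genes)
  strand <- sample(c("+", "-"), n_genes, replace = TRUE)
  tss <- as.integer((seq_len(n_genes) - 1) * slot + floor(slot / 2))
  dirn <- ifelse(strand == "+", 1L, -1L)
  gene_len <- as.integer(n_nucs_per_side * spacing + ndr_offset)
  genes <- data.frame(
    gene_id = sprintf("gene%04d", seq_len(n_genes)),
    chrom = chrom, strand = strand, tss = tss,
    tes = tss + dirn * gene_len,
    rpkm_A = round(stats::rlnorm(n_genes, meanlog = 1, sdlog = 1.5), 3),
    stringsAsFactors = FALSE)
  genes$rpkm_B <- genes$rpkm_A
  roles <- c(seq_len(n_nucs_per_side), -seq_len(n_nucs_per_side))
  truth <- do.call(rbind, lapply(seq_len(n_genes), function(i) {
    plus1 <- tss[i] + dirn[i] * ndr_offset
    minus1 <- plus1 - dirn[i] * (ndr_width + 0L)
    dy <- ifelse(roles > 0,
                 plus1 + dirn[i] * (roles - 1L) * spacing,
                 minus1 - dirn[i] * (abs(roles) - 1L) * spacing)
    data.frame(condition = "A", gene_id = genes$gene_id[i], role = roles,
               dyad = as.integer(dy), delta = 0L, direction = "none",
               stringsAsFactors = FALSE)
  }))
  truthB <- truth
  truthB$condition <- "B"
  truth <- rbind(truth, truthB)
  rownames(truth) <- NULL
  seqv <- .random_sequence(chrom_len, gc_fraction)
  if (nuc_gc_fraction != gc_fraction) {
    dyA <- unique(truth$dyad[truth$condition == "A"])
    for (d in dyA) {
      lo <- max(0L, d - 73L); hi <- min(chrom_len - 1L, d + 73L)
      seqv[(lo + 1):(hi + 1)] <- .random_sequence(hi - lo + 1L, nuc_gc_fraction)
    }
  }
  sequence <- paste(seqv, collapse = "")
  names(sequence) <- NULL
  model <- list(sequence = stats::setNames(sequence, chrom),
                chrom = chrom, chrom_len = as.integer(chrom_len),
                genes = genes, truth = truth,
                ndr_width = ndr_width, spacing = spacing,
                ndr_offset = ndr_offset,
                n_nucs_per_side = n_nucs_per_side, seed = seed)
  class(model) <- "GenomeModel"
  model
}

.random_sequence <- function(n, gc) {
  sample(c("A", "T", "G", "C"), n, replace = TRUE,
         prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2))
}

#' @export
print.GenomeModel <- function(x, ...) {
  cat("GenomeModel: ", x$chrom_len, " bp, ", nrow(x$genes), " genes, ",
      "spacing ", x$spacing, " bp, NDR ", x$ndr_width, " bp\n", sep = "")
  invisible(x)
}

#' Program condition-specific dyad shifts into a genome model
#'
#' Moves the condition-B ground-truth dyad of targeted (gene, role) entries
#' by `delta` bp in the stated gene-oriented direction (downstream =
#' towards the gene body). Only the +1 and -1 roles may be targeted, and
#' deltas must not exceed the array spacing so the array order is preserved.
#' Untargeted entries keep identical dyads in both conditions.
#'
#' @param model a `GenomeModel`.
#' @param programs data.frame with columns `gene_id`, `role` (+1 or -1),
#'   `direction` (`"upstream"`/`"downstream"`), `delta` (bp > 0) and
#'   optionally `condition` (default `"B"`).
#' @return The updated `GenomeModel`; applied deltas are recorded verbatim
#'   in the truth table.
#' @export
program_shifts <- function(model, programs) {
  stopifnot(inherits(model, "GenomeModel"))
  if (is.null(programs) || nrow(programs) == 0) return(model)
  stopifnot(all(c("gene_id", "role", "direction", "delta") %in% names(programs)))
  if (!all(programs$role %in% c(1L, -1L)))
    stop("shift programs may only target the +1 and -1 roles")
  if (any(programs$delta <= 0)) stop("deltas must be positive")
  if (any(programs$delta > model$spacing))
    stop("deltas must not exceed the array spacing (", model$spacing, " bp)")
  cond <- if ("condition" %in% names(programs)) programs$condition else
    rep("B", nrow(programs))
  for (i in seq_len(nrow(programs))) {
    g <- programs$gene_id[i]
    gi <- match(g, model$genes$gene_id)
    if (is.na(gi)) stop("shift program targets unknown gene: ", g)
    dirn <- if (model$genes$strand[gi] == "+") 1L else -1L
    sgn <- if (programs$direction[i] == "downstream") 1L else -1L
    j <- which(model$truth$condition == cond[i] &
                 model$truth$gene_id == g &
                 model$truth$role == programs$role[i])
    stopifnot(length(j) == 1L)
    model$truth$dyad[j] <- model$truth$dyad[j] +
      as.integer(dirn * sgn * programs$delta[i])
    model$truth$delta[j] <- as.integer(programs$delta[i])
    model$truth$direction[j] <- programs$direction[i]
  }
  model
}

#' Sample MNase fragments from a genome model's ground truth
#'
#' For each truth dyad of the requested condition, emits `depth_per_nuc`
#' fragments whose center is the dyad plus rounded gaussian jitter and whose
#' length is a rounded gaussian clamped to [100, 250] bp (the bounded
#' support of a mononucleosome gel cut). Fragments that would extend past
#' the chromosome are dropped. `total_count` is the emitted fragment count.
#'
#' @param model a `GenomeModel`.
#' @param condition `"A"` or `"B"`.
#' @param depth_per_nuc fragments per nucleosome.
#' @param len_mean,len_sd fragment length distribution (bp).
#' @param dyad_jitter_sd positional jitter of fragment centers (bp).
#' @param seed integer seed.
#' @return A `FragmentSet` labelled with the condition.
#' @export
sample_fragments <- function(model, condition = "A", depth_per_nuc = 50,
                             len_mean = 147, len_sd = 12,
                             dyad_jitter_sd = 10, seed = 1) {
  stopifnot(inherits(model, "GenomeModel"), depth_per_nuc >= 1)
  set.seed(seed)
  dy <- model$truth$dyad[model$truth$condition == condition]
  if (!length(dy)) stop("no truth dyads for condition ", condition)
  n <- length(dy) * depth_per_nuc
  center <- rep(dy, each = depth_per_nuc) +
    round(stats::rnorm(n, 0, dyad_jitter_sd))
  len <- pmin(pmax(round(stats::rnorm(n, len_mean, len_sd)), 100), 250)
  start <- center - floor((len - 1) / 2)
  end <- start + len
  keep <- start >= 0 & end <= model$chrom_len
  df <- data.frame(chrom = model$chrom, start = as.integer(start[keep]),
                   end = as.integer(end[keep]), length = as.integer(len[keep]),
                   stringsAsFactors = FALSE)
  fragment_set(df, total_count = nrow(df), sample_label = condition)
}

#' Export the ground-truth dyad table as TSV
#'
#' One row per (condition, gene, role) with the applied shift delta (0 for
#' unprogrammed entries) and direction.
#'
#' @param model a `GenomeModel`.
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
export_truth <- function(model, path) {
  stopifnot(inherits(model, "GenomeModel"))
  df <- model$truth[, c("condition", "gene_id", "role", "dyad", "delta",
                        "direction")]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a ground-truth dyad table written by [export_truth()]
#' @param path TSV file.
#' @return data.frame of truth rows.
#' @export
read_truth <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write TSS anchors of a genome model as BED6
#' @param model a `GenomeModel`.
#' @param path output BED file.
#' @return `path`, invisibly.
#' @export
write_tss_bed <- function(model, path) {
  g <- model$genes
  # BED6 point interval whose annotated start site equals the TSS on both
  # strands: [tss, tss+1) with the strand column carrying orientation
  df <- data.frame(chrom = g$chrom, start = g$tss, end = g$tss + 1L,
                   name = g$gene_id, score = 0L, strand = g$strand)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
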