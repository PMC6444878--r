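#' Quantify tag density over regions (RPBM)
#'
#' Counts tags (fragment dyads, or pre-computed points) falling in each
#' region `[start, end)` and converts to RPBM
#' (`count * 1e6 / total tags`), with a pseudocounted log2 value for
#' plotting-scale comparisons.
#'
#' @param tags a `FragmentSet` (dyads are used) or a data.frame with
#'   `chrom`, `position`.
#' @param regions data.frame with `chrom`, `start`, `end` (0-based
#'   half-open) and optionally `name`.
#' @param total total tag count; defaults to the FragmentSet's
#'   `total_count` or the number of points.
#' @param pseudocount offset inside the log2.
#' @return data.frame: region columns plus `count`, `rpbm`, `log2_rpbm`.
#' @export
quantify_signal <- function(tags, regions, total = NULL, pseudocount = 1) {
  if (inherits(tags, "FragmentSet")) {
    pts <- data.frame(chrom = tags$fragments$chrom, position = dyads(tags))
    if (is.null(total)) total <- tags$total_count
  } else {
    pts <- tags
    if (is.null(total)) total <- nrow(pts)
  }
  if (total <= 0) stop("total tag count must be positive")
  if (any(regions$end <= regions$start)) stop("zero-length region")
  count <- integer(nrow(regions))
  for (i in seq_len(nrow(regions))) {
    count[i] <- sum(pts$chrom == regions$chrom[i] &
                      pts$position >= regions$start[i] &
                      pts$position < regions$end[i])
  }
  out <- regions
  out$count <- count
  out$rpbm <- count * 1e6 / total
  out$log2_rpbm <- log2(out$rpbm + pseudocount)
  out
}

#' Two-sample Kolmogorov-Smirnov comparison of group densities
#'
#' Two-sided KS test; the p-value is exact (permutation-equivalent) when
#' both samples have at most 10 observations and asymptotic otherwise.
#'
#' @param values_a,values_b numeric samples.
#' @return A `GroupComparison` list: `D`, `p_value`, `n_a`, `n_b`, and
#'   type-7 quartile summaries per sample.
#' @export
ks_compare <- function(values_a, values_b) {
  if (!length(values_a) || !length(values_b)) stop("empty sample")
  exact <- length(values_a) <= 10 && length(values_b) <= 10
  kt <- suppressWarnings(stats::ks.test(values_a, values_b, exact = exact))
  structure(list(D = unname(kt$statistic), p_value = kt$p.value,
                 n_a = length(values_a), n_b = length(values_b),
                 summary_a = stats::quantile(values_a, type = 7),
                 summary_b = stats::quantile(values_b, type = 7)),
            class = "GroupComparison")
}

#' Per-group quartile summary table
#'
#' @param values numeric vector.
#' @param groups grouping vector (same length); groups listed in `levels`
#'   but absent from the data get an all-NA row with n = 0.
#' @param levels optional group ordering.
#' @return data.frame: `group`, `min`, `q1`, `median`, `q3`, `max`, `n`
#'   (type-7 quartiles).
#' @export
group_summary <- function(values, groups, levels = NULL) {
  if (is.null(levels)) levels <- unique(groups)
  rows <- lapply(levels, function(g) {
    v <- values[groups == g & !is.na(values)]
    if (!length(v))
      return(data.frame(group = g, min = NA_real_, q1 = NA_real_,
                        median = NA_real_, q3 = NA_real_, max = NA_real_,
                        n = 0L))
    q <- stats::quantile(v, c(0, 0.25, 0.5, 0.75, 1), type = 7, names = FALSE)
    data.frame(group = g, min = q[1], q1 = q[2], median = q[3], q3 = q[4],
               max = q[5], n = length(v))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Associate shift groups with differential expression
#'
#' For each (role, direction, bin) shift group, the fraction of member genes
#' called up- or downregulated. Genes absent from the DE table are counted
#' as unchanged (the number is reported in the `n_missing_de` attribute).
#' Aggregate rows per role pool the 10-50 through 151-200 bins (the
#' "shifted 10-200 bp" stratum) across directions, alongside the uniform
#' (0-bp) row.
#'
#' @param shift_table data.frame from [gene_shift_table()].
#' @param de DE data.frame from [read_de_table()] (columns `gene_id`,
#'   `status`).
#' @return data.frame: `role`, `direction`, `bin`, `n`, `fraction_up`,
#'   `fraction_down`.
#' @export
de_shift_association <- function(shift_table, de) {
  st <- shift_table[!shift_table$bin %in% c("unmatched", "excluded"), ,
                    drop = FALSE]
  status <- de$status[match(st$gene_id, de$gene_id)]
  n_missing <- sum(is.na(status))
  status[is.na(status)] <- "unchanged"
  frac_row <- function(role, direction, bin, sel) {
    n <- sum(sel)
    data.frame(role = role, direction = direction, bin = bin, n = n,
               fraction_up = if (n) sum(status[sel] == "up") / n else NA_real_,
               fraction_down = if (n) sum(status[sel] == "down") / n else NA_real_,
               stringsAsFactors = FALSE)
  }
  rows <- list()
  for (role in sort(unique(st$role), decreasing = TRUE)) {
    for (bin in intersect(shift_bins(FALSE), unique(st$bin[st$role == role]))) {
      for (dirn in unique(st$direction[st$role == role & st$bin == bin])) {
        sel <- st$role == role & st$bin == bin & st$direction == dirn
        rows[[length(rows) + 1L]] <- frac_row(role, dirn, bin, sel)
      }
    }
    pooled <- st$role == role &
      st$bin %in% c("10-50", "51-100", "101-150", "151-200")
    if (any(pooled))
      rows[[length(rows) + 1L]] <- frac_row(role, "any", "10-200", pooled)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "n_missing_de") <- n_missing
  out
}

#' Binding enrichment of shifted versus uniformly placed nucleosomes
#'
#' A nucleosome is "bound" when its summit lies inside any bound region
#' (`mode = "summit"`, default) or when its 147-bp footprint overlaps one
#' (`mode = "overlap"`). Reports the bound fraction per group and the fold
#' change of each group's fraction over the reference (0-bp shift) group.
#'
#' @param positions data.frame with `group`, `chrom`, `summit`.
#' @param bound_regions data.frame with `chrom`, `start`, `end`.
#' @param mode `"summit"` or `"overlap"`.
#' @param reference reference group label (default `"0"`).
#' @return data.frame: `group`, `n`, `n_bound`, `fraction_bound`,
#'   `fold_vs_reference` (NA when the reference fraction is 0).
#' @export
binding_enrichment <- function(positions, bound_regions,
                               mode = c("summit", "overlap"),
                               reference = "0") {
  mode <- match.arg(mode)
  is_bound <- logical(nrow(positions))
  for (i in seq_len(nrow(positions))) {
    sel <- bound_regions$chrom == positions$chrom[i]
    if (!any(sel)) next
    s <- positions$summit[i]
    lo <- if (mode == "summit") s else s - 73L
    hi <- if (mode == "summit") s else s + 73L
    is_bound[i] <- any(bound_regions$start[sel] <= hi &
                         bound_regions$end[sel] > lo)
  }
  groups <- unique(positions$group)
  rows <- lapply(groups, function(g) {
    sel <- positions$group == g
    data.frame(group = g, n = sum(sel), n_bound = sum(is_bound[sel]),
               fraction_bound = mean(is_bound[sel]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  ref <- out$fraction_bound[out$group == reference]
  out$fold_vs_reference <- if (length(ref) == 1 && !is.na(ref) && ref > 0)
    out$fraction_bound / ref else NA_real_
  rownames(out) <- NULL
  out
}
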