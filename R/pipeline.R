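#' Default pipeline configuration
#'
#' Every tunable parameter of the pipeline with its default. The defaults
#' are the package's standing analysis choices: canonical fragment window
#' 140-180 bp, gaussian smoothing sigma 20 bp, 147-bp footprints with
#' 120-bp minimum summit separation, 1-kb profile flanks, and the standard
#' shift strata.
#'
#' @param seed integer seed used by every stochastic stage.
#' @param outdir output directory.
#' @return nested list of class `RunConfig`.
#' @export
default_config <- function(seed = 1, outdir = "nucshift_out") {
  structure(list(
    seed = seed,
    outdir = outdir,
    paths = list(fragments_A = NULL, fragments_B = NULL, anchors = NULL,
                 genome = NULL, signal = NULL, de_table = NULL),
    simulate = list(n_genes = 60, chrom_len = 400000, gc_fraction = 0.5,
                    nuc_gc_fraction = 0.5, ndr_width = 150, spacing = 190,
                    n_nucs_per_side = 3, ndr_offset = 100,
                    depth_per_nuc = 50, len_mean = 147, len_sd = 12,
                    dyad_jitter_sd = 10,
                    shift_deltas = c(30, 75, 125, 175),
                    shift_fraction = 0.5),
    canonical = list(lo = 140, hi = 180),
    occupancy = list(bandwidth = 20, kernel = "gaussian", flank = 1000),
    caller = list(min_occupancy = 1, min_summit_distance = 55),
    diff = list(window = 147),
    shift = list(window = 1000, max_shift = 200),
    seqfeat = list(flank = 100, k = 6, kmer_window = 10, kmer_flank = 130,
                   promoter_upstream = 1000, promoter_downstream = 100),
    integrate = list(pseudocount = 1, fc_threshold = 1.5,
                     fdr_threshold = 0.001)
  ), class = "RunConfig")
}

#' Read a pipeline configuration from YAML
#'
#' Values present in the file override the defaults of
#' [default_config()]; everything else keeps its default, so a config file
#' only needs the parameters it changes.
#'
#' @param path YAML file.
#' @return A `RunConfig`.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- default_config()
  merge_in <- function(base, upd) {
    for (k in names(upd)) {
      base[[k]] <- if (is.list(base[[k]]) && is.list(upd[[k]]))
        merge_in(base[[k]], upd[[k]]) else upd[[k]]
    }
    base
  }
  structure(merge_in(unclass(cfg), user), class = "RunConfig")
}

#' Write a pipeline configuration to YAML
#' @param config a `RunConfig`.
#' @param path output YAML file.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in dependency order
#' (simulate, occupancy, call, diff, shift, seqfeat, integrate), writing
#' every output as a plain-text file under `config$outdir` and returning a
#' manifest of files with md5 checksums. Two runs with the same config and
#' seed produce byte-identical outputs. A stage whose inputs are missing
#' stops with an error naming the stage to run first.
#'
#' @param config a `RunConfig` (see [default_config()]).
#' @param stages character vector; subset of
#'   `c("simulate","occupancy","call","diff","shift","seqfeat","integrate")`
#'   or `"all"`.
#' @return list with `status` (0 on success) and `manifest` (data.frame of
#'   `file`, `md5`).
#' @export
run_pipeline <- function(config = default_config(),
                         stages = "all") {
  all_stages <- c("simulate", "occupancy", "call", "diff", "shift",
                  "seqfeat", "integrate")
  if (identical(stages, "all")) stages <- all_stages
  unknown <- setdiff(stages, all_stages)
  if (length(unknown)) stop("unknown stage(s): ", paste(unknown, collapse = ", "))
  stages <- all_stages[all_stages %in% stages]
  if (!length(stages))
    return(list(status = 0L, manifest = data.frame(file = character(),
                                                   md5 = character())))
  out <- config$outdir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(out, ...)
  need <- function(files, stage_needed) {
    miss <- files[!file.exists(files)]
    if (length(miss))
      stop("missing input(s) ", paste(basename(miss), collapse = ", "),
           ": run the '", stage_needed, "' stage first")
  }
  written <- character(0)
  emit <- function(path) written <<- c(written, path)

  if ("simulate" %in% stages) {
    if (is.null(config$seed)) stop("a seed is mandatory for the simulate stage")
    s <- config$simulate
    model <- simulate_genome(n_genes = s$n_genes, chrom_len = s$chrom_len,
                             gc_fraction = s$gc_fraction,
                             nuc_gc_fraction = s$nuc_gc_fraction,
                             ndr_width = s$ndr_width, spacing = s$spacing,
                             n_nucs_per_side = s$n_nucs_per_side,
                             ndr_offset = s$ndr_offset, seed = config$seed)
    model <- program_shifts(model, make_shift_programs(
      model, deltas = s$shift_deltas, fraction = s$shift_fraction,
      seed = config$seed + 1L))
    fragsA <- sample_fragments(model, "A", depth_per_nuc = s$depth_per_nuc,
                               len_mean = s$len_mean, len_sd = s$len_sd,
                               dyad_jitter_sd = s$dyad_jitter_sd,
                               seed = config$seed + 2L)
    fragsB <- sample_fragments(model, "B", depth_per_nuc = s$depth_per_nuc,
                               len_mean = s$len_mean, len_sd = s$len_sd,
                               dyad_jitter_sd = s$dyad_jitter_sd,
                               seed = config$seed + 3L)
    emit(write_genome_fasta(model$sequence, p("genome.fa")))
    emit(write_tss_bed(model, p("tss.bed")))
    emit(write_fragments_bed(fragsA, p("fragments_A.bed")))
    emit(write_fragments_bed(fragsB, p("fragments_B.bed")))
    emit(export_truth(model, p("truth.tsv")))
    write.table(model$genes, p("genes.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    emit(p("genes.tsv"))
    emit(.write_synthetic_de(model, p("de_table.tsv"), seed = config$seed + 4L))
  }

  frag_path <- function(cond) {
    cfgp <- config$paths[[paste0("fragments_", cond)]]
    if (!is.null(cfgp)) cfgp else p(paste0("fragments_", cond, ".bed"))
  }
  anchor_path <- if (!is.null(config$paths$anchors)) config$paths$anchors else p("tss.bed")
  genes_path <- p("genes.tsv")
  load_inputs <- function() {
    need(c(frag_path("A"), frag_path("B"), anchor_path), "simulate")
    list(A = read_fragments(frag_path("A"), sample_label = "A"),
         B = read_fragments(frag_path("B"), sample_label = "B"),
         anchors = read_anchors(anchor_path, "TSS"))
  }
  canonical_tracks <- function(inp) {
    clen <- NULL
    if (file.exists(p("genome.fa"))) {
      g <- read_genome(p("genome.fa"))
      clen <- stats::setNames(nchar(g), names(g))
    }
    lapply(inp[c("A", "B")], function(fr) {
      can <- filter_canonical(fr, config$canonical$lo, config$canonical$hi)
      dyad_density(can, "dyad", chrom_lengths = clen)
    })
  }

  if ("occupancy" %in% stages) {
    inp <- load_inputs()
    tracks <- canonical_tracks(inp)
    for (cond in c("A", "B")) {
      sm <- smooth_track(rpbm_normalize(tracks[[cond]]),
                         config$occupancy$bandwidth, config$occupancy$kernel)
      emit(write_track(sm, p(sprintf("occupancy_%s.bedgraph", cond))))
      prof <- profile_1d(sm, inp$anchors, config$occupancy$flank)
      emit(write_profile(prof, p(sprintf("profile_tss_%s.tsv", cond))))
      fl <- fragment_length_density(inp[[cond]])
      write.table(fl, p(sprintf("fragment_lengths_%s.tsv", cond)),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      emit(p(sprintf("fragment_lengths_%s.tsv", cond)))
    }
  }

  if ("call" %in% stages) {
    inp <- load_inputs()
    tracks <- canonical_tracks(inp)
    for (cond in c("A", "B")) {
      can <- filter_canonical(inp[[cond]], config$canonical$lo,
                              config$canonical$hi)
      sm <- smooth_track(rpbm_normalize(tracks[[cond]]),
                         config$occupancy$bandwidth, config$occupancy$kernel)
      calls <- call_nucleosomes(sm, config$caller$min_occupancy,
                                config$caller$min_summit_distance,
                                frags = can, sample_label = cond)
      emit(write_nucleosome_calls(calls, p(sprintf("calls_%s.tsv", cond))))
    }
  }

  if ("diff" %in% stages) {
    inp <- load_inputs()
    tracks <- canonical_tracks(inp)
    dt <- positional_difference(tracks$A, tracks$B,
                                totalA = inp$A$total_count,
                                totalB = inp$B$total_count,
                                window = config$diff$window)
    emit(write_track(dt, p("positional_difference.bedgraph")))
  }

  if ("shift" %in% stages) {
    need(c(p("calls_A.tsv"), p("calls_B.tsv")), "call")
    need(genes_path, "simulate")
    callsA <- read_nucleosome_calls(p("calls_A.tsv"))
    callsB <- read_nucleosome_calls(p("calls_B.tsv"))
    genes <- utils::read.delim(genes_path, stringsAsFactors = FALSE)
    st <- gene_shift_table(callsA, callsB, genes,
                           window = config$shift$window,
                           max_shift = config$shift$max_shift)
    write.table(st, p("shift_table.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    emit(p("shift_table.tsv"))
    pairs <- pair_nucleosomes(callsA, callsB)
    sp <- spacing_distances(callsA)
    un <- uniformness(sp$distances)
    summary <- data.frame(
      metric = c("n_pairs", "region_variance_bp", "spacing_mode_bp",
                 "spacing_iqr_bp"),
      value = c(nrow(pairs), region_variance(pairs), un$mode, un$iqr))
    write.table(summary, p("shift_summary.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    emit(p("shift_summary.tsv"))
  }

  if ("seqfeat" %in% stages) {
    need(c(p("genome.fa"), p("calls_A.tsv")), "call")
    need(genes_path, "simulate")
    genome <- read_genome(p("genome.fa"))
    calls <- read_nucleosome_calls(p("calls_A.tsv"))
    genes <- utils::read.delim(genes_path, stringsAsFactors = FALSE)
    sites <- data.frame(chrom = calls$chrom, position = calls$summit,
                        strand = "+")
    comp <- dinucleotide_profile(genome, sites, config$seqfeat$flank)
    emit(write_composition_profile(comp, p("composition_profile.tsv")))
    ann <- annotate_genic(data.frame(chrom = calls$chrom,
                                     position = calls$summit),
                          genes, config$seqfeat$promoter_upstream,
                          config$seqfeat$promoter_downstream)
    tb <- as.data.frame(table(annotation = ann), stringsAsFactors = FALSE)
    write.table(tb, p("annotation_counts.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    emit(p("annotation_counts.tsv"))
  }

  if ("integrate" %in% stages) {
    need(p("shift_table.tsv"), "shift")
    de_path <- if (!is.null(config$paths$de_table)) config$paths$de_table
               else p("de_table.tsv")
    need(de_path, "simulate")
    st <- utils::read.delim(p("shift_table.tsv"), stringsAsFactors = FALSE)
    st$bin <- as.character(st$bin)
    de <- read_de_table(de_path, config$integrate$fc_threshold,
                        config$integrate$fdr_threshold)
    assoc <- de_shift_association(st, de)
    write.table(assoc, p("de_association.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    emit(p("de_association.tsv"))
  }

  manifest <- data.frame(file = basename(written),
                         md5 = unname(tools::md5sum(written)),
                         stringsAsFactors = FALSE)
  manifest <- manifest[order(manifest$file), ]
  rownames(manifest) <- NULL
  write.table(manifest, p("manifest.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  list(status = 0L, manifest = manifest)
}

#' Build a standard shift-program table for a simulated genome
#'
#' Selects a fraction of genes (seeded), splits them evenly across the
#' requested shift magnitudes, and alternates downstream/upstream direction
#' within each magnitude, targeting the +1 nucleosome.
#'
#' @param model a `GenomeModel`.
#' @param deltas shift magnitudes in bp.
#' @param fraction fraction of genes to shift.
#' @param role targeted role (+1 or -1).
#' @param seed integer seed for the gene draw.
#' @return data.frame suitable for [program_shifts()].
#' @export
make_shift_programs <- function(model, deltas = c(30, 75, 125, 175),
                                fraction = 0.5, role = 1L, seed = 1) {
  set.seed(seed)
  n <- max(0L, round(nrow(model$genes) * fraction))
  if (n == 0L)
    return(data.frame(gene_id = character(), role = integer(),
                      direction = character(), delta = numeric()))
  picked <- sort(sample(model$genes$gene_id, n))
  data.frame(gene_id = picked, role = role,
             direction = rep_len(c("downstream", "upstream"), n),
             delta = rep_len(rep(deltas, each = 2), n),
             stringsAsFactors = FALSE)
}

# Synthetic DE table for demo/integration runs: statuses drawn per gene.
.write_synthetic_de <- function(model, path, seed = 1,
                                p_up = 0.15, p_down = 0.15) {
  set.seed(seed)
  g <- model$genes
  status <- sample(c("up", "down", "unchanged"), nrow(g), replace = TRUE,
                   prob = c(p_up, p_down, 1 - p_up - p_down))
  log2fc <- ifelse(status == "up", stats::runif(nrow(g), 1, 3),
                   ifelse(status == "down", stats::runif(nrow(g), -3, -1),
                          stats::runif(nrow(g), -0.4, 0.4)))
  fdr <- ifelse(status == "unchanged", stats::runif(nrow(g), 0.01, 1),
                stats::runif(nrow(g), 0, 0.0009))
  df <- data.frame(gene_id = g$gene_id, log2fc = round(log2fc, 4),
                   fdr = signif(fdr, 4), rpkm = g$rpkm_A)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
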