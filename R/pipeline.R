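## End-to-end orchestration: simulate -> call -> classify -> annotate ->
## cohort -> differential, driven by a nested config (YAML file or list).
## All randomness flows from the single config seed; outputs are plain TSV
## plus a text report, so every report number is recomputable from the
## stage files it summarizes.

#' Default demo pipeline configuration
#'
#' A desk-scale cohort: four chromosomes totalling 4.2 Mb, two groups of
#' 7 samples, 60 master loci with group-specific presence probabilities, and
#' junction evidence deep enough for the caller to recover planted circles.
#'
#' @param seed master seed.
#' @param out_dir output directory.
#' @return nested configuration list.
#' @export
default_pipeline_config <- function(seed = 1L, out_dir = tempfile("eccrun")) {
  list(
    seed = seed,
    out_dir = out_dir,
    simulate = list(
      chromosomes = list(chr1 = 1500000, chr2 = 1200000, chr3 = 900000,
                         chr4 = 600000),
      genes_per_mb = 12,
      n_circles = 60,
      junction_read_depth = 6,
      background_depth = 3,
      gene_density_coupling = TRUE,
      n_case = 7, n_control = 7,
      presence_prob = list(AIONFH = 0.45, control = 0.6)
    ),
    caller = list(min_structural_reads = 2, min_split = 1),
    confidence = list(min_coverage_fraction = 0.80, min_edge_ratio = 0.5),
    context = list(flank_bp = 2000, window_bp = 50000),
    cohort = list(min_samples = 2, tolerance_bp = 0,
                  size_cutoff_bp = 100000, smoothing_bandwidth_bp = 25),
    differential = list(pseudocount = 0.001, alpha = 0.05,
                        min_abs_log2fc = 1, normalization = "total",
                        test = "ranksum")
  )
}

#' Validate a pipeline configuration
#'
#' Total function: returns every violation found, not just the first; an
#' empty character vector means the config is valid.
#'
#' @param config nested config list (see [default_pipeline_config()]) or a
#'   YAML file path.
#' @return character vector of error messages (empty when valid).
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) return(paste("config file not found:", config))
    config <- yaml::read_yaml(config)
  }
  errs <- character()
  need <- function(cond, msg) if (!isTRUE(cond)) errs <<- c(errs, msg)
  need(is.numeric(config$seed) && length(config$seed) == 1,
       "seed: must be a single number")
  sim <- config$simulate
  need(is.list(sim), "simulate: section missing")
  if (is.list(sim)) {
    need(length(sim$chromosomes) >= 1 &&
           all(unlist(sim$chromosomes) > 0),
         "simulate.chromosomes: need >= 1 chromosome with positive length")
    need(is.numeric(sim$n_circles) && sim$n_circles >= 1,
         "simulate.n_circles: must be >= 1")
    need(is.numeric(sim$junction_read_depth) && sim$junction_read_depth >= 0,
         "simulate.junction_read_depth: must be >= 0")
    need(is.numeric(sim$background_depth) && sim$background_depth >= 0,
         "simulate.background_depth: must be >= 0")
    need(sim$n_case >= 1 && sim$n_control >= 1,
         "simulate.n_case/n_control: both groups must be non-empty")
    pp <- unlist(sim$presence_prob)
    need(all(pp >= 0 & pp <= 1),
         "simulate.presence_prob: probabilities must lie in [0, 1]")
  }
  dif <- config$differential
  if (is.list(dif)) {
    need(dif$alpha > 0 && dif$alpha < 1,
         "differential.alpha: must lie in (0, 1)")
    need(dif$pseudocount > 0, "differential.pseudocount: must be > 0")
    need(dif$min_abs_log2fc >= 0,
         "differential.min_abs_log2fc: must be >= 0")
  }
  coh <- config$cohort
  if (is.list(coh)) {
    need(coh$min_samples >= 1, "cohort.min_samples: must be >= 1")
    need(coh$tolerance_bp >= 0, "cohort.tolerance_bp: must be >= 0")
  }
  errs
}

#' Run the whole pipeline
#'
#' Stages run in dependency order: cohort simulation, per-sample junction
#' calling, confidence classification, genomic-context annotation, cohort
#' statistics (size classes, length peaks, consistency, group overlap,
#' density correlations) and per-gene differential analysis. Every stage
#' writes its table under `config$out_dir`; the returned list carries the
#' same objects. The report summarizes counts per size class and tier,
#' per-group length peaks, the region distribution, per-group density
#' correlations, overlap counts and the differential outcome.
#'
#' @param config nested config list or YAML path
#'   (see [default_pipeline_config()]).
#' @return invisibly, a list with all stage results and `report` (character
#'   vector of report lines).
#' @export
run_pipeline <- function(config = default_pipeline_config()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  errs <- validate_config(config)
  if (length(errs)) {
    stop("invalid pipeline config:\n  ", paste(errs, collapse = "\n  "))
  }
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sim <- config$simulate
  cfg <- sim_config(
    seed = config$seed,
    chromosomes = data.frame(chrom = names(sim$chromosomes),
                             length = unlist(sim$chromosomes)),
    genes_per_mb = sim$genes_per_mb, n_circles = sim$n_circles,
    background_depth = sim$background_depth,
    junction_read_depth = sim$junction_read_depth,
    gene_density_coupling = isTRUE(sim$gene_density_coupling))
  ## --- simulate ---
  gen <- generate_genome(cfg)
  annotation <- generate_annotation(gen$index, cfg)
  truth <- plant_circles(gen$index, annotation, cfg)
  ## keep the demo at read scale: junction reads need len > read length
  manifest <- data.frame(
    sample_id = c(sprintf("A%02d", seq_len(sim$n_case)),
                  sprintf("C%02d", seq_len(sim$n_control))),
    group = c(rep("AIONFH", sim$n_case), rep("control", sim$n_control)),
    path = NA_character_, stringsAsFactors = FALSE)
  write_genome_index(gen$index, file.path(out_dir, "genome_index.tsv"))
  write_gene_models_gff3(annotation, file.path(out_dir, "genes.gff3"))
  write_truth(truth, file.path(out_dir, "truth.tsv"))
  ## --- per-sample: presence, reads, calling, classification ---
  params <- caller_params(
    min_structural_reads = config$caller$min_structural_reads,
    min_split = config$caller$min_split)
  rules <- confidence_rules(
    min_coverage_fraction = config$confidence$min_coverage_fraction,
    min_edge_ratio = config$confidence$min_edge_ratio)
  pp <- sim$presence_prob
  calls_by_sample <- list()
  for (si in seq_len(nrow(manifest))) {
    sid <- manifest$sample_id[si]
    grp <- manifest$group[si]
    present <- circle_presence(truth, cfg, si, pp[[grp]])
    recs <- suppressWarnings(
      simulate_reads(truth, gen$genome, cfg, sample_id = sid,
                     circles = truth$circles[present, , drop = FALSE]))
    sam <- file.path(out_dir, paste0("sample_", sid, ".sam"))
    write_sam(recs, gen$index, sam)
    manifest$path[si] <- sam
    calls <- call_circles(sam, gen$genome, gen$index, params,
                          sample_id = sid,
                          insert_mean_bp = cfg$insert_mean_bp,
                          insert_sd_bp = cfg$insert_sd_bp)
    calls <- suppressWarnings(add_confidence_tier(calls, rules))
    write.table(calls, file.path(out_dir, paste0("calls_", sid, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    calls_by_sample[[sid]] <- calls
  }
  ## manifest on disk carries paths relative to its own directory
  rel <- manifest
  rel$path <- basename(rel$path)
  write_manifest(rel, file.path(out_dir, "manifest.tsv"))
  pooled <- do.call(rbind, calls_by_sample)
  rownames(pooled) <- NULL
  ## --- cohort statistics ---
  coh <- config$cohort
  sizes <- partition_by_size(pooled, coh$size_cutoff_bp)
  tiers <- summarize_tiers(pooled, rules)
  peaks <- lapply(split(pooled, manifest$group[match(pooled$sample_id,
                                                    manifest$sample_id)]),
                  function(tab) {
                    if (nrow(tab) == 0L) return(NA_real_)
                    length_histogram(
                      tab, smoothing_bandwidth_bp =
                        coh$smoothing_bandwidth_bp)$peak_bp
                  })
  loci <- merge_locus_identity(pooled, coh$tolerance_bp)
  consistent <- lapply(setNames(GROUP_LABELS, GROUP_LABELS), function(g) {
    consistency_filter(loci, manifest, g, coh$min_samples)
  })
  venn <- venn_counts(consistent$AIONFH, consistent$control,
                      coh$tolerance_bp)
  densities <- lapply(setNames(GROUP_LABELS, GROUP_LABELS), function(g) {
    ids <- manifest$sample_id[manifest$group == g]
    density_per_chromosome(pooled[pooled$sample_id %in% ids, , drop = FALSE],
                           gen$index, annotation)
  })
  correlations <- lapply(densities, function(d) {
    tryCatch(correlate_density(d), error = function(e) NULL)
  })
  regions <- region_distribution(pooled, annotation,
                                 config$context$flank_bp, gen$index)
  ## --- differential ---
  dif <- config$differential
  dcfg <- differential_config(pseudocount = dif$pseudocount,
                              alpha = dif$alpha,
                              min_abs_log2fc = dif$min_abs_log2fc,
                              normalization = dif$normalization,
                              test = dif$test)
  mat <- gene_count_matrix(calls_by_sample, annotation)
  diff_tab <- run_differential(mat, manifest, dcfg)
  sig <- significant_genes(diff_tab, dcfg)
  write.table(loci, file.path(out_dir, "loci.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(diff_tab, file.path(out_dir, "differential.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  ## --- report ---
  fmt_corr <- function(cr) {
    if (is.null(cr)) return("undefined (constant density vector)")
    sprintf("r = %.3f, p = %.4f (n = %d chromosomes)", cr$r, cr$p, cr$n)
  }
  report <- c(
    "eccatlas pipeline report",
    sprintf("seed: %d", config$seed),
    sprintf("samples: %d AIONFH + %d control", sim$n_case, sim$n_control),
    sprintf("planted circles: %d; pooled calls: %d", nrow(truth$circles),
            nrow(pooled)),
    sprintf("size classes: %d eccDNA (<= %d bp), %d ecDNA",
            nrow(sizes$eccdna), coh$size_cutoff_bp, nrow(sizes$ecdna)),
    sprintf("confidence tiers: lconf %d, conf %d, hconf %d", tiers["lconf"],
            tiers["conf"], tiers["hconf"]),
    sprintf("length peak (bp): AIONFH %s, control %s",
            format(peaks$AIONFH), format(peaks$control)),
    sprintf("cohort loci: %d; consistent (>= %d samples): AIONFH %d, control %d",
            nrow(loci), coh$min_samples, nrow(consistent$AIONFH),
            nrow(consistent$control)),
    sprintf("group overlap: only AIONFH %d, only control %d, both %d",
            venn$only_a, venn$only_b, venn$both),
    sprintf("region distribution: %s",
            paste(names(regions), regions, sep = "=", collapse = ", ")),
    sprintf("density vs gene density: AIONFH %s; control %s",
            fmt_corr(correlations$AIONFH), fmt_corr(correlations$control)),
    sprintf("differential: %d genes tested, %d significant (%d up, %d down)",
            nrow(diff_tab), nrow(sig$table), sig$n_up, sig$n_down)
  )
  writeLines(report, file.path(out_dir, "report.txt"))
  invisible(list(config = config, manifest = manifest, truth = truth,
                 calls_by_sample = calls_by_sample, pooled = pooled,
                 sizes = sizes, tiers = tiers, peaks = peaks, loci = loci,
                 consistent = consistent, venn = venn,
                 densities = densities, correlations = correlations,
                 regions = regions, count_matrix = mat,
                 differential = diff_tab, significant = sig,
                 report = report))
}
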