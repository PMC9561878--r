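## Synthetic Circle-seq-like data: genomes, gene annotations, planted circles
## and junction-supporting paired-end alignments. Every operation is a pure
## function of (config, seed): the RNG state is saved and restored around each.

with_sim_seed <- function(seed, offset, expr) {
  if (!is.numeric(seed) || is.na(seed)) stop("config must carry a seed")
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed((as.integer(seed) + offset) %% .Machine$integer.max)
  force(expr)
}

#' Simulation configuration
#'
#' Bundles every knob of the synthetic Circle-seq cohort. The circle-length
#' model is a three-part mixture: a lognormal body whose mode sits at
#' `mode_bp` (the field's reported peak for small eccDNA is ~358 bp), a
#' uniform tail of kb-scale circles, and a rare ecDNA band of 100 kb-1 Mb
#' elements. Defaults place ~86% of the mass below 3 kb and ~0.1% in the
#' ecDNA band, matching the size structure typical of somatic-tissue
#' Circle-seq cohorts.
#'
#' @param seed integer master seed (keep below 2^31).
#' @param chromosomes `data.frame` with columns `chrom`, `length` (bp).
#' @param genes_per_mb scalar or per-chromosome named vector of gene rates.
#' @param n_circles total number of circles to plant.
#' @param mode_bp mode of the lognormal length component, bp.
#' @param sigma lognormal shape (sd of log length).
#' @param tail_fraction mixture weight of the uniform kb-scale tail.
#' @param tail_min_bp,tail_max_bp bounds of the uniform tail.
#' @param ecdna_fraction mixture weight of the ecDNA band (in \[0,1\]).
#' @param ecdna_min_bp,ecdna_max_bp bounds of the ecDNA band.
#' @param min_length_bp hard lower bound on circle length.
#' @param read_length_bp,insert_mean_bp,insert_sd_bp read/fragment geometry.
#' @param background_depth mean genome-wide depth of concordant background
#'   pairs.
#' @param junction_read_depth junction-supporting records (split +
#'   discordant) per planted circle; with a value of at least 2, every circle
#'   gets at least one of each kind.
#' @param gene_density_coupling logical; when `TRUE`, per-chromosome circle
#'   counts are allocated proportionally to realized gene counts, emulating a
#'   positive circles-per-Mb vs genes-per-Mb correlation.
#' @param gene_length_range bp range gene bodies are drawn from.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       chromosomes = data.frame(
                         chrom = paste0("chr", 1:4),
                         length = c(1500000, 1200000, 900000, 600000)),
                       genes_per_mb = 12,
                       n_circles = 200L,
                       mode_bp = 358,
                       sigma = 0.75,
                       tail_fraction = 0.13,
                       tail_min_bp = 3000,
                       tail_max_bp = 100000,
                       ecdna_fraction = 0.0011,
                       ecdna_min_bp = 100500,
                       ecdna_max_bp = 998830,
                       min_length_bp = 50,
                       read_length_bp = 100,
                       insert_mean_bp = 300,
                       insert_sd_bp = 30,
                       background_depth = 2,
                       junction_read_depth = 4,
                       gene_density_coupling = FALSE,
                       gene_length_range = c(2000, 20000)) {
  cfg <- list(seed = seed, chromosomes = genome_index(chromosomes$chrom,
                                                      chromosomes$length),
              genes_per_mb = genes_per_mb, n_circles = as.integer(n_circles),
              mode_bp = mode_bp, sigma = sigma,
              tail_fraction = tail_fraction, tail_min_bp = tail_min_bp,
              tail_max_bp = tail_max_bp, ecdna_fraction = ecdna_fraction,
              ecdna_min_bp = ecdna_min_bp, ecdna_max_bp = ecdna_max_bp,
              min_length_bp = min_length_bp,
              read_length_bp = read_length_bp,
              insert_mean_bp = insert_mean_bp, insert_sd_bp = insert_sd_bp,
              background_depth = background_depth,
              junction_read_depth = junction_read_depth,
              gene_density_coupling = isTRUE(gene_density_coupling),
              gene_length_range = gene_length_range)
  if (cfg$mode_bp <= 0) stop("mode_bp must be positive")
  if (cfg$ecdna_fraction < 0 || cfg$ecdna_fraction > 1) {
    stop("ecdna_fraction must lie in [0, 1]")
  }
  if (cfg$tail_fraction < 0 || cfg$tail_fraction + cfg$ecdna_fraction > 1) {
    stop("mixture weights must be non-negative and sum to at most 1")
  }
  if (cfg$background_depth < 0 || cfg$junction_read_depth < 0) {
    stop("depths must be non-negative")
  }
  if (cfg$read_length_bp >= cfg$insert_mean_bp) {
    stop("read_length_bp must be smaller than insert_mean_bp")
  }
  class(cfg) <- "sim_config"
  cfg
}

#' Draw circle lengths from the mixture length model
#' @param n number of lengths.
#' @param config a [sim_config()].
#' @return integer vector of lengths (bp).
#' @export
sample_circle_lengths <- function(n, config) {
  u <- runif(n)
  len <- numeric(n)
  ec <- u < config$ecdna_fraction
  tl <- !ec & u < config$ecdna_fraction + config$tail_fraction
  body <- !ec & !tl
  len[ec] <- runif(sum(ec), config$ecdna_min_bp, config$ecdna_max_bp)
  len[tl] <- runif(sum(tl), config$tail_min_bp, config$tail_max_bp)
  ## lognormal parameterized through its mode: mode = exp(meanlog - sdlog^2)
  len[body] <- rlnorm(sum(body),
                      meanlog = log(config$mode_bp) + config$sigma^2,
                      sdlog = config$sigma)
  pmax(as.integer(round(len)), as.integer(config$min_length_bp))
}

#' Generate a random genome
#'
#' Uniform random nucleotides per chromosome; deterministic for a given
#' config seed.
#'
#' @param config a [sim_config()].
#' @return list with `genome` (a [Biostrings::DNAStringSet]) and `index`
#'   (genome index `data.frame`).
#' @export
generate_genome <- function(config) {
  idx <- config$chromosomes
  if (nrow(idx) == 0L) stop("config has zero chromosomes")
  with_sim_seed(config$seed, 101L, {
    seqs <- vapply(idx$length, function(len) {
      paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
    }, character(1))
    genome <- Biostrings::DNAStringSet(seqs)
    names(genome) <- idx$chrom
    list(genome = genome, index = idx)
  })
}

#' Generate a random non-overlapping gene annotation
#'
#' Per-chromosome gene counts are Poisson with rate `genes_per_mb` x length;
#' gene bodies are placed uniformly without overlap (bounded retries), each
#' with 1-10 exons whose first/last boundaries coincide with the gene ends.
#'
#' @param index genome index `data.frame`.
#' @param config a [sim_config()].
#' @return A [gene_models()] object.
#' @export
generate_annotation <- function(index, config) {
  rate <- config$genes_per_mb
  if (!is.null(names(rate))) {
    missing <- setdiff(index$chrom, names(rate))
    if (length(missing)) stop("genes_per_mb missing for: ",
                              paste(missing, collapse = ", "))
    rate <- rate[index$chrom]
  } else {
    rate <- rep(rate, nrow(index))
  }
  with_sim_seed(config$seed, 202L, {
    genes <- list(); exons <- list(); gi <- 0L
    for (ci in seq_len(nrow(index))) {
      chrlen <- index$length[ci]
      n <- rpois(1, rate[ci] * chrlen / 1e6)
      if (n == 0L) next
      placed <- IRanges::IRanges()
      tries <- 0L
      while (length(placed) < n) {
        tries <- tries + 1L
        if (tries > 60L * n) stop("gene placement failed on ", index$chrom[ci],
                                  ": rate too high for non-overlap")
        glen <- round(runif(1, config$gene_length_range[1],
                            min(config$gene_length_range[2], chrlen - 1)))
        gstart <- floor(runif(1, 0, chrlen - glen))
        cand <- IRanges::IRanges(gstart + 1L, gstart + glen)
        if (length(placed) == 0L ||
            !any(IRanges::overlapsAny(cand, placed))) {
          placed <- c(placed, cand)
          gi <- gi + 1L
          id <- sprintf("G%04d", gi)
          strand <- sample(c("+", "-"), 1)
          genes[[gi]] <- data.frame(gene_id = id, chrom = index$chrom[ci],
                                    start = gstart, end = gstart + glen,
                                    strand = strand, stringsAsFactors = FALSE)
          n_ex <- sample(1:10, 1)
          if (n_ex == 1L || glen < 4L * n_ex) {
            ex <- data.frame(gene_id = id, start = gstart, end = gstart + glen)
          } else {
            brk <- sort(sample(seq(gstart + 1L, gstart + glen - 1L),
                               2L * (n_ex - 1L)))
            bnd <- c(gstart, brk, gstart + glen)
            ex <- data.frame(gene_id = id,
                             start = bnd[seq(1, length(bnd), by = 2)],
                             end = bnd[seq(2, length(bnd), by = 2)])
          }
          exons[[gi]] <- ex
        }
      }
    }
    if (gi == 0L) {
      return(gene_models(
        data.frame(gene_id = character(), chrom = character(),
                   start = numeric(), end = numeric(), strand = character(),
                   stringsAsFactors = FALSE),
        data.frame(gene_id = character(), start = numeric(), end = numeric(),
                   stringsAsFactors = FALSE)))
    }
    gene_models(do.call(rbind, genes), do.call(rbind, exons))
  })
}

#' Plant circles on a genome
#'
#' Circle lengths come from the mixture model in the config. Per-chromosome
#' counts are multinomial with weights proportional to chromosome length, or
#' to realized gene counts when `gene_density_coupling` is on.
#'
#' @param index genome index `data.frame`.
#' @param annotation a [gene_models()] object (used for coupling weights).
#' @param config a [sim_config()].
#' @return A `synthetic_truth` list with `circles`
#'   (`circle_id, chrom, start, end, length, copy_weight`), `gene_models`,
#'   and `index`.
#' @export
plant_circles <- function(index, annotation, config) {
  n <- config$n_circles
  weights <- if (config$gene_density_coupling) {
    tab <- table(factor(annotation$genes$chrom, levels = index$chrom))
    as.numeric(tab)
  } else {
    index$length
  }
  if (sum(weights) <= 0) stop("all chromosome weights are zero")
  with_sim_seed(config$seed, 303L, {
    chrom_idx <- sample(seq_len(nrow(index)), n, replace = TRUE,
                        prob = weights / sum(weights))
    chrlen <- index$length[chrom_idx]
    len <- sample_circle_lengths(n, config)
    tries <- 0L
    while (any(len >= chrlen)) {   # resample circles longer than their chrom
      tries <- tries + 1L
      if (tries > 100L) {
        stop("cannot place circle(s): chromosome shorter than sampled lengths")
      }
      bad <- len >= chrlen
      len[bad] <- sample_circle_lengths(sum(bad), config)
    }
    start <- floor(runif(n) * (chrlen - len))
    truth <- list(
      circles = data.frame(
        circle_id = sprintf("C%04d", seq_len(n)),
        chrom = index$chrom[chrom_idx], start = start, end = start + len,
        length = len, copy_weight = 1, stringsAsFactors = FALSE),
      gene_models = annotation, index = index)
    class(truth) <- "synthetic_truth"
    truth
  })
}

#' Write planted-circle ground truth as TSV
#' @param truth a `synthetic_truth` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  write.table(truth$circles, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

seq_window <- function(genome, chrom, start0, end0) {
  as.character(Biostrings::subseq(genome[[chrom]], start0 + 1L, end0))
}

#' Simulate junction-supporting and background alignments
#'
#' Three record classes are emitted: (a) genome-wide concordant background
#' pairs at `background_depth`; (b) junction-crossing split reads written as
#' soft-clipped alignments whose clipped prefix/suffix equals the sequence
#' entering the opposite circle edge; (c) outward-oriented discordant pairs
#' straddling the junction (reverse-strand mate near the circle start,
#' forward-strand mate near the end). Each circle receives
#' `junction_read_depth` junction records split between (b) and (c), with at
#' least one of each when the depth is at least 2. Read names encode the
#' originating circle id, so every junction read maps to exactly one planted
#' circle. Circles shorter than the read length get no junction reads (a
#' warning is logged).
#'
#' @param truth a `synthetic_truth` from [plant_circles()].
#' @param genome a [Biostrings::DNAStringSet] from [generate_genome()].
#' @param config a [sim_config()].
#' @param sample_id read-group-like tag baked into read names.
#' @param circles optional subset of `truth$circles` to emit evidence for
#'   (cohort presence/absence); defaults to all.
#' @return A coordinate-sorted `data.frame` of SAM records (one row per
#'   alignment line).
#' @export
simulate_reads <- function(truth, genome, config, sample_id = "S1",
                           circles = NULL) {
  if (is.null(circles)) circles <- truth$circles
  idx <- truth$index
  L <- config$read_length_bp
  chrom_str <- setNames(as.character(genome[idx$chrom]), idx$chrom)
  win <- function(chrom, start0, end0) {
    substring(chrom_str[[chrom]], start0 + 1, end0)
  }
  empty <- data.frame(qname = character(), flag = integer(),
                      rname = character(), pos = integer(), mapq = integer(),
                      cigar = character(), rnext = character(),
                      pnext = integer(), tlen = integer(), seq = character(),
                      stringsAsFactors = FALSE)
  recs <- list()
  with_sim_seed(config$seed, 404L + sum(utf8ToInt(sample_id)), {
    ## background concordant inward-facing pairs, vectorized per chromosome
    if (config$background_depth > 0) {
      for (ci in seq_len(nrow(idx))) {
        chrlen <- idx$length[ci]; chrom <- idx$chrom[ci]
        npair <- round(config$background_depth * chrlen / (2 * L))
        if (npair <= 0) next
        ins <- pmax(2L * L, round(rnorm(npair, config$insert_mean_bp,
                                        config$insert_sd_bp)))
        p0 <- floor(runif(npair, 0, pmax(1, chrlen - ins)))
        m0 <- p0 + ins - L
        qn <- sprintf("bg_%s_%s_%d", sample_id, chrom, seq_len(npair))
        recs[[length(recs) + 1L]] <- data.frame(
          qname = c(qn, qn), flag = rep(c(99L, 147L), each = npair),
          rname = chrom, pos = c(p0, m0) + 1L, mapq = 60L,
          cigar = paste0(L, "M"), rnext = "=", pnext = c(m0, p0) + 1L,
          tlen = c(ins, -ins),
          seq = c(win(chrom, p0, p0 + L), win(chrom, m0, m0 + L)),
          stringsAsFactors = FALSE)
      }
    }
    ## junction evidence per circle
    clip_min <- 10L
    for (i in seq_len(nrow(circles))) {
      crc <- circles[i, ]
      len <- crc$end - crc$start
      n_j <- round(config$junction_read_depth * crc$copy_weight)
      if (n_j <= 0) next
      if (L >= len || L < 2L * clip_min) {
        warning("circle ", crc$circle_id, " shorter than read length; ",
                "junction reads skipped")
        next
      }
      n_split <- if (n_j >= 2L) max(1L, ceiling(n_j / 2)) else n_j
      n_disc <- n_j - n_split
      if (n_j >= 2L && n_disc == 0L) { n_disc <- 1L; n_split <- n_j - 1L }
      s <- crc$start; e <- crc$end; chrom <- crc$chrom
      k <- seq_len(n_split)
      m <- sample(seq(clip_min, L - clip_min), n_split, replace = TRUE)
      at_end <- k %% 2L == 1L   # aligned at circle end, 3' clip -> start
      recs[[length(recs) + 1L]] <- data.frame(
        qname = sprintf("split_%s_%s_%d", sample_id, crc$circle_id, k),
        flag = 0L, rname = chrom,
        pos = ifelse(at_end, e - m + 1L, s + 1L), mapq = 60L,
        cigar = ifelse(at_end, paste0(m, "M", L - m, "S"),
                       paste0(L - m, "S", m, "M")),
        rnext = "*", pnext = 0L, tlen = 0L,
        seq = ifelse(at_end,
                     paste0(win(chrom, e - m, e), win(chrom, s, s + L - m)),
                     paste0(win(chrom, e - (L - m), e),
                            win(chrom, s, s + m))),
        stringsAsFactors = FALSE)
      if (n_disc > 0L) {
        span <- max(1L, min(config$insert_mean_bp - L, len - L))
        pR <- pmin(s + floor(runif(n_disc, 0, span)), e - L)
        pF <- pmax(e - L - floor(runif(n_disc, 0, span)), s)
        ## circles shorter than the insert can invert the draws; the
        ## outward orientation always has the reverse mate leftmost
        lo <- pmin(pR, pF); hi <- pmax(pR, pF)
        eq <- hi == lo
        hi[eq] <- pmin(hi[eq] + 1L, e - L)
        lo[eq] <- pmax(pmin(lo[eq], hi[eq] - 1L), s)
        pR <- lo; pF <- hi
        qn <- sprintf("disc_%s_%s_%d", sample_id, crc$circle_id,
                      seq_len(n_disc))
        recs[[length(recs) + 1L]] <- data.frame(
          qname = c(qn, qn), flag = rep(c(81L, 161L), each = n_disc),
          rname = chrom, pos = c(pR, pF) + 1L, mapq = 60L,
          cigar = paste0(L, "M"), rnext = "=", pnext = c(pF, pR) + 1L,
          tlen = 0L,
          seq = c(vapply(seq_len(n_disc),
                         function(j) win(chrom, pR[j], pR[j] + L),
                         character(1)),
                  vapply(seq_len(n_disc),
                         function(j) win(chrom, pF[j], pF[j] + L),
                         character(1))),
          stringsAsFactors = FALSE)
      }
    }
    out <- if (length(recs)) do.call(rbind, recs) else empty
    ord <- order(match(out$rname, idx$chrom), out$pos, out$qname)
    out <- out[ord, , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}

#' Write SAM records (with header) to a file
#' @param records record `data.frame` from [simulate_reads()].
#' @param index genome index `data.frame` (for the `@SQ` header lines).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(records, index, path) {
  header <- c("@HD\tVN:1.6\tSO:coordinate",
              sprintf("@SQ\tSN:%s\tLN:%d", index$chrom,
                      as.integer(index$length)))
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t%d\t%s\t*",
                  records$qname, records$flag, records$rname, records$pos,
                  records$mapq, records$cigar, records$rnext, records$pnext,
                  records$tlen, records$seq)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Draw which master loci are present in one sample
#'
#' Deterministic Bernoulli presence per locus, seeded by the config seed and
#' the sample index, so a cohort's per-sample subsets are reproducible
#' one-by-one.
#'
#' @param truth `synthetic_truth` with the master loci.
#' @param config a [sim_config()] (seed source).
#' @param sample_index 1-based index of the sample in the cohort.
#' @param prob per-locus presence probability.
#' @return logical vector over `truth$circles` rows.
#' @export
circle_presence <- function(truth, config, sample_index, prob) {
  with_sim_seed(config$seed, 600L + as.integer(sample_index), {
    runif(nrow(truth$circles)) < prob
  })
}

#' Simulate a cohort of per-sample call tables (no reads)
#'
#' Call-level cohort generator used by the cohort-statistics and differential
#' stages: a master set of planted loci is shared across samples, each locus
#' is present in a sample with a per-group Bernoulli probability, and an
#' optional set of differentially abundant genes receives per-sample Poisson
#' circle counts inside the gene body at group-specific rates. Emitted calls
#' carry evidence metrics drawn to be classifiable (split support >= 1).
#'
#' @param truth `synthetic_truth` with the master loci.
#' @param manifest sample manifest `data.frame`.
#' @param config a [sim_config()] (seed source).
#' @param presence_prob named vector `c(AIONFH = , control = )` of per-locus
#'   presence probabilities.
#' @param de optional `data.frame` with columns `gene_id`, `rate_case`,
#'   `rate_control`: per-sample Poisson means of extra circles planted inside
#'   each listed gene body.
#' @return named list of circle-call `data.frame`s, one per sample.
#' @export
simulate_cohort_calls <- function(truth, manifest, config,
                                  presence_prob = c(AIONFH = 0.45,
                                                    control = 0.6),
                                  de = NULL) {
  manifest <- validate_manifest(manifest)
  circles <- truth$circles
  genes <- truth$gene_models$genes
  with_sim_seed(config$seed, 505L, {
    out <- list()
    for (si in seq_len(nrow(manifest))) {
      grp <- manifest$group[si]
      keep <- runif(nrow(circles)) < presence_prob[[grp]]
      tab <- circles[keep, , drop = FALSE]
      extra <- NULL
      if (!is.null(de) && nrow(de)) {
        rows <- list()
        for (gi in seq_len(nrow(de))) {
          g <- genes[genes$gene_id == de$gene_id[gi], ]
          if (nrow(g) == 0L) stop("de gene not in annotation: ",
                                  de$gene_id[gi])
          rate <- if (grp == "AIONFH") de$rate_case[gi] else
            de$rate_control[gi]
          nc <- rpois(1, rate)
          if (nc == 0L) next
          len <- pmin(sample_circle_lengths(nc, config),
                      as.integer(g$end - g$start - 1L))
          st <- floor(runif(nc, g$start, g$end - len))
          rows[[length(rows) + 1L]] <- data.frame(
            chrom = g$chrom, start = st, end = st + len,
            stringsAsFactors = FALSE)
        }
        if (length(rows)) extra <- do.call(rbind, rows)
      }
      n_all <- nrow(tab) + if (is.null(extra)) 0L else nrow(extra)
      chrom <- c(tab$chrom, extra$chrom)
      start <- c(tab$start, extra$start)
      end <- c(tab$end, extra$end)
      calls <- circle_call_table(
        chrom = chrom, start = start, end = end,
        n_split = 1L + rpois(n_all, 2),
        n_discordant = 1L + rpois(n_all, 2),
        coverage_fraction = pmin(1, stats::rbeta(n_all, 9, 1.2)),
        cov_increase_start = pmin(1, stats::rbeta(n_all, 6, 2)),
        cov_increase_end = pmin(1, stats::rbeta(n_all, 6, 2)),
        sample_id = manifest$sample_id[si])
      ord <- order(match(calls$chrom, truth$index$chrom), calls$start,
                   calls$end)
      out[[manifest$sample_id[si]]] <- calls[ord, , drop = FALSE]
    }
    out
  })
}
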