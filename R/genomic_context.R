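## Genic-region attribution, per-gene counting and per-chromosome densities.
## Region classes: exon, intron, gene_up2k, gene_down2k, intergenic, with
## precedence exon > intron > gene_up2k > gene_down2k > intergenic (a call
## gets the highest-precedence class it overlaps by >= 1 bp). The 2 kb
## flanks are strand-aware: up2k sits 5' of the gene body.

REGION_CLASSES <- c("exon", "intron", "gene_up2k", "gene_down2k",
                    "intergenic")

calls_granges <- function(calls) {
  GenomicRanges::GRanges(calls$chrom,
                         IRanges::IRanges(calls$start + 1L, calls$end))
}

region_granges <- function(models, flank_bp = 2000L, index = NULL) {
  g <- models$genes
  e <- models$exons
  e$chrom <- g$chrom[match(e$gene_id, g$gene_id)]
  gr_gene <- GenomicRanges::GRanges(g$chrom,
                                    IRanges::IRanges(g$start + 1L, g$end))
  gr_exon <- if (nrow(e)) {
    GenomicRanges::GRanges(e$chrom, IRanges::IRanges(e$start + 1L, e$end))
  } else GenomicRanges::GRanges()
  gr_intron <- GenomicRanges::setdiff(gr_gene, gr_exon)
  plus <- g$strand == "+"
  up_start <- ifelse(plus, g$start - flank_bp, g$end)
  up_end <- ifelse(plus, g$start, g$end + flank_bp)
  dn_start <- ifelse(plus, g$end, g$start - flank_bp)
  dn_end <- ifelse(plus, g$end + flank_bp, g$start)
  clip <- function(s, e, chrom) {
    s <- pmax(s, 0)
    if (!is.null(index)) {
      e <- pmin(e, index$length[match(chrom, index$chrom)])
    }
    keep <- e > s
    GenomicRanges::GRanges(chrom[keep],
                           IRanges::IRanges(s[keep] + 1L, e[keep]))
  }
  list(exon = gr_exon, intron = gr_intron,
       gene_up2k = clip(up_start, up_end, g$chrom),
       gene_down2k = clip(dn_start, dn_end, g$chrom),
       gene_body = gr_gene)
}

#' Classify calls by genic-region origin
#'
#' @param calls circle-call `data.frame`.
#' @param models a [gene_models()] object.
#' @param flank_bp flank width for the up/down classes (default 2000).
#' @param index optional genome index used to clip flanks at chromosome ends.
#' @return factor of region classes, one per call.
#' @export
classify_region <- function(calls, models, flank_bp = 2000L, index = NULL) {
  if (nrow(calls) == 0L) {
    return(factor(character(), levels = REGION_CLASSES))
  }
  gr <- calls_granges(calls)
  regions <- region_granges(models, flank_bp, index)
  out <- rep("intergenic", nrow(calls))
  for (cls in c("gene_down2k", "gene_up2k", "intron", "exon")) {
    ## calls on annotation-free chromosomes share no seqlevels: still
    ## intergenic, not an error
    hit <- suppressWarnings(IRanges::overlapsAny(gr, regions[[cls]]))
    out[hit] <- cls
  }
  factor(out, levels = REGION_CLASSES)
}

#' Count calls per genic-region class
#'
#' @inheritParams classify_region
#' @return named integer vector over the five region classes; sums to
#'   `nrow(calls)`.
#' @export
region_distribution <- function(calls, models, flank_bp = 2000L,
                                index = NULL) {
  cls <- classify_region(calls, models, flank_bp, index)
  out <- table(cls)
  setNames(as.integer(out), REGION_CLASSES)
}

#' Count circles per gene for one sample
#'
#' In `overlap` mode (the default) a call increments every gene body it
#' overlaps by >= 1 bp; in `containment` mode only genes fully containing
#' the call are incremented.
#'
#' @param calls circle-call `data.frame` for one sample.
#' @param models a [gene_models()] object.
#' @param mode `"overlap"` or `"containment"`.
#' @return named integer vector, one entry per gene (zeros included).
#' @export
count_per_gene <- function(calls, models, mode = c("overlap",
                                                   "containment")) {
  mode <- match.arg(mode)
  g <- models$genes
  counts <- setNames(integer(nrow(g)), g$gene_id)
  if (nrow(calls) == 0L || nrow(g) == 0L) return(counts)
  gr_gene <- GenomicRanges::GRanges(g$chrom,
                                    IRanges::IRanges(g$start + 1L, g$end))
  gr <- calls_granges(calls)
  type <- if (mode == "overlap") "any" else "within"
  n <- suppressWarnings(GenomicRanges::countOverlaps(gr_gene, gr,
                                                     type = type))
  counts[] <- as.integer(n)
  counts
}

#' Build a gene x sample circle-count matrix
#'
#' @param calls_by_sample named list of per-sample call tables.
#' @param models a [gene_models()] object.
#' @param mode passed to [count_per_gene()].
#' @return integer matrix, rows = genes, columns = samples.
#' @export
gene_count_matrix <- function(calls_by_sample, models, mode = "overlap") {
  cols <- lapply(calls_by_sample, count_per_gene, models = models,
                 mode = mode)
  mat <- do.call(cbind, cols)
  colnames(mat) <- names(calls_by_sample)
  mat
}

#' Per-chromosome circle density and gene density
#'
#' @param calls circle-call `data.frame`.
#' @param index genome index `data.frame`; one output row per chromosome,
#'   zero-count chromosomes included.
#' @param models a [gene_models()] object.
#' @return `data.frame` with `chrom`, `length_bp`, `n_circles`,
#'   `circles_per_mb`, `n_genes`, `genes_per_mb`.
#' @export
density_per_chromosome <- function(calls, index, models) {
  unknown <- setdiff(unique(calls$chrom), index$chrom)
  if (length(unknown)) {
    stop("call on chromosome absent from genome index: ",
         paste(unknown, collapse = ", "))
  }
  n_circ <- table(factor(calls$chrom, levels = index$chrom))
  n_gene <- table(factor(models$genes$chrom, levels = index$chrom))
  mb <- index$length / 1e6
  data.frame(chrom = index$chrom, length_bp = index$length,
             n_circles = as.integer(n_circ),
             circles_per_mb = as.integer(n_circ) / mb,
             n_genes = as.integer(n_gene),
             genes_per_mb = as.integer(n_gene) / mb,
             stringsAsFactors = FALSE)
}

#' Pearson correlation of circle density with gene density
#'
#' Two-sided p-value from the t transform with n - 2 degrees of freedom
#' (via [stats::cor.test()]).
#'
#' @param density output of [density_per_chromosome()], or any `data.frame`
#'   with `circles_per_mb` and `genes_per_mb`.
#' @return list `(r, p, n)`.
#' @export
correlate_density <- function(density) {
  pearson_correlation(density$circles_per_mb, density$genes_per_mb)
}

pearson_correlation <- function(x, y) {
  if (length(x) < 3L) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined for a constant vector")
  }
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Fixed-width window counts of circles along the genome
#'
#' Generic binning (default 50 kb windows) behind the genome-wide density
#' scan; the last window of each chromosome is truncated at its end.
#'
#' @param calls circle-call `data.frame`.
#' @param index genome index `data.frame`.
#' @param window_bp window width in bp.
#' @return `data.frame` with `chrom`, `start`, `end`, `n_circles` (a call is
#'   counted in every window it overlaps).
#' @export
window_density <- function(calls, index, window_bp = 50000L) {
  rows <- lapply(seq_len(nrow(index)), function(ci) {
    starts <- seq(0, index$length[ci] - 1, by = window_bp)
    data.frame(chrom = index$chrom[ci], start = starts,
               end = pmin(starts + window_bp, index$length[ci]),
               stringsAsFactors = FALSE)
  })
  win <- do.call(rbind, rows)
  gr_win <- GenomicRanges::GRanges(win$chrom,
                                   IRanges::IRanges(win$start + 1L, win$end))
  win$n_circles <- if (nrow(calls)) {
    suppressWarnings(GenomicRanges::countOverlaps(gr_win,
                                                  calls_granges(calls)))
  } else 0L
  win
}
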