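## Cohort-level characterization: the 100 kb eccDNA/ecDNA size split,
## length-distribution peaks, cross-sample locus identity, the
## consistency-in->=2-samples rule, group overlap (Venn) counts, and the
## between-group per-gene quantity correlation.

#' Partition calls at the eccDNA/ecDNA size cutoff
#'
#' Elements longer than the cutoff (strictly greater) are ecDNA; a length of
#' exactly 100 kb is still eccDNA. The split is disjoint and exhaustive.
#'
#' @param calls circle-call `data.frame`.
#' @param cutoff_bp size cutoff (default 100000).
#' @return list with `eccdna` and `ecdna` call tables.
#' @export
partition_by_size <- function(calls, cutoff_bp = 100000) {
  len <- calls$end - calls$start
  list(eccdna = calls[len <= cutoff_bp, , drop = FALSE],
       ecdna = calls[len > cutoff_bp, , drop = FALSE])
}

#' Length histogram with kernel-smoothed peak
#'
#' Counts lengths in `bin_width_bp` bins (default 1 bp, the resolution at
#' which circle-length peaks are reported) and locates the peak as the
#' argmax of Gaussian-kernel-smoothed counts; near-ties (within a 1e-9
#' relative tolerance) break toward the smaller length.
#'
#' @param lengths numeric vector of circle lengths (bp), or a circle-call
#'   `data.frame`.
#' @param bin_width_bp histogram bin width.
#' @param smoothing_bandwidth_bp Gaussian kernel sd in bp (default 25).
#' @return list of class `length_histogram`: `breaks` (left bin edges),
#'   `counts`, `smoothed`, `peak_bp`, `bin_width_bp`,
#'   `smoothing_bandwidth_bp`.
#' @export
length_histogram <- function(lengths, bin_width_bp = 1,
                             smoothing_bandwidth_bp = 25) {
  if (is.data.frame(lengths)) lengths <- lengths$end - lengths$start
  if (!length(lengths)) stop("length_histogram needs at least one call")
  lo <- floor(min(lengths) / bin_width_bp) * bin_width_bp
  hi <- floor(max(lengths) / bin_width_bp) * bin_width_bp
  breaks <- seq(lo, hi, by = bin_width_bp)
  idx <- floor((lengths - lo) / bin_width_bp) + 1L
  counts <- tabulate(idx, nbins = length(breaks))
  half <- max(1L, ceiling(4 * smoothing_bandwidth_bp / bin_width_bp))
  kx <- (-half:half) * bin_width_bp
  kern <- exp(-0.5 * (kx / smoothing_bandwidth_bp)^2)
  kern <- kern / sum(kern)
  padded <- c(numeric(half), counts, numeric(half))
  filt <- as.numeric(stats::filter(padded, kern, sides = 2))
  smoothed <- filt[(half + 1L):(half + length(counts))]
  peak_idx <- min(which(smoothed >= max(smoothed) * (1 - 1e-9)))
  structure(list(breaks = breaks, counts = counts, smoothed = smoothed,
                 peak_bp = breaks[peak_idx], bin_width_bp = bin_width_bp,
                 smoothing_bandwidth_bp = smoothing_bandwidth_bp),
            class = "length_histogram")
}

#' @export
print.length_histogram <- function(x, ...) {
  cat("length_histogram: ", sum(x$counts), " lengths in [",
      min(x$breaks), ", ", max(x$breaks) + x$bin_width_bp, ") bp; peak at ",
      x$peak_bp, " bp (bandwidth ", x$smoothing_bandwidth_bp, " bp)\n",
      sep = "")
  invisible(x)
}

#' Merge per-sample calls into cohort loci
#'
#' Calls from different samples are the "same eccDNA" iff they sit on the
#' same chromosome and both |delta start| and |delta end| are within
#' `tolerance_bp`; loci are the connected components of this relation,
#' represented by their leftmost member (smallest start, then smallest end).
#' The default tolerance of 0 makes identity exact coordinates.
#'
#' @param calls circle-call `data.frame` pooling >= 1 sample.
#' @param tolerance_bp coordinate tolerance (default 0).
#' @return `data.frame` with `locus_id`, `chrom`, `start`, `end`,
#'   `n_samples`, `n_calls`, `sample_ids` (comma-joined); plus a `members`
#'   attribute mapping row index of `calls` to `locus_id`.
#' @export
merge_locus_identity <- function(calls, tolerance_bp = 0) {
  if (nrow(calls) == 0L) {
    out <- data.frame(locus_id = character(), chrom = character(),
                      start = numeric(), end = numeric(),
                      n_samples = integer(), n_calls = integer(),
                      sample_ids = character(), stringsAsFactors = FALSE)
    attr(out, "members") <- integer(0)
    return(out)
  }
  n <- nrow(calls)
  comp <- seq_len(n)
  find <- function(i) { while (comp[i] != i) i <- comp[i]; i }
  union_ <- function(i, j) comp[find(j)] <<- find(i)
  if (tolerance_bp == 0) {
    key <- paste(calls$chrom, calls$start, calls$end, sep = ":")
    first <- match(key, key)
    for (i in seq_len(n)) if (first[i] != i) union_(first[i], i)
  } else {
    ord <- order(calls$chrom, calls$start, calls$end)
    for (a in seq_len(n - 1L)) {
      i <- ord[a]
      b <- a + 1L
      while (b <= n) {
        j <- ord[b]
        if (calls$chrom[j] != calls$chrom[i] ||
            calls$start[j] - calls$start[i] > tolerance_bp) break
        if (abs(calls$end[j] - calls$end[i]) <= tolerance_bp) union_(i, j)
        b <- b + 1L
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  locus_of <- match(roots, unique(roots))
  rows <- lapply(seq_along(unique(roots)), function(k) {
    m <- which(locus_of == k)
    lead <- m[order(calls$start[m], calls$end[m])][1L]
    ids <- sort(unique(calls$sample_id[m]))
    data.frame(chrom = calls$chrom[lead], start = calls$start[lead],
               end = calls$end[lead], n_samples = length(ids),
               n_calls = length(m),
               sample_ids = paste(ids, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  ord <- order(out$chrom, out$start, out$end)
  out <- out[ord, , drop = FALSE]
  out$locus_id <- sprintf("L%05d", seq_len(nrow(out)))
  out <- out[c("locus_id", "chrom", "start", "end", "n_samples", "n_calls",
               "sample_ids")]
  rownames(out) <- NULL
  attr(out, "members") <- order(ord)[locus_of]
  out
}

#' Keep loci detected in at least `min_samples` samples of one group
#'
#' The cohort consistency rule: a circle is interpreted at cohort level only
#' when detected in at least two samples of the same group.
#'
#' @param loci locus table from [merge_locus_identity()].
#' @param manifest sample manifest `data.frame`.
#' @param group group label to filter for.
#' @param min_samples minimum samples of that group (default 2).
#' @return subset of `loci`.
#' @export
consistency_filter <- function(loci, manifest, group, min_samples = 2L) {
  manifest <- validate_manifest(manifest)
  if (!group %in% manifest$group) stop("unknown or empty group: ", group)
  in_group <- manifest$sample_id[manifest$group == group]
  n_in <- vapply(strsplit(loci$sample_ids, ",", fixed = TRUE),
                 function(ids) sum(ids %in% in_group), integer(1))
  loci[n_in >= min_samples, , drop = FALSE]
}

#' Group-overlap (Venn) counts of two locus sets
#'
#' Loci are matched across the two sets with the same identity rule used to
#' build them; with tolerance > 0, counts come from connected components of
#' the pooled sets (a component containing members of both sets counts as
#' `both`). Satisfies `only_a + only_b + both = |A U B|`.
#'
#' @param loci_a,loci_b locus tables ([merge_locus_identity()]).
#' @param tolerance_bp coordinate tolerance (default 0).
#' @return list `(only_a, only_b, both)`.
#' @export
venn_counts <- function(loci_a, loci_b, tolerance_bp = 0) {
  pool <- rbind(
    data.frame(chrom = loci_a$chrom, start = loci_a$start,
               end = loci_a$end,
               sample_id = rep("setA", nrow(loci_a)),
               stringsAsFactors = FALSE),
    data.frame(chrom = loci_b$chrom, start = loci_b$start,
               end = loci_b$end,
               sample_id = rep("setB", nrow(loci_b)),
               stringsAsFactors = FALSE))
  pool$length <- pool$end - pool$start
  pool$n_split <- 0L; pool$n_discordant <- 0L
  pool$coverage_fraction <- 0; pool$cov_increase_start <- 0
  pool$cov_increase_end <- 0
  if (nrow(pool) == 0L) return(list(only_a = 0L, only_b = 0L, both = 0L))
  merged <- merge_locus_identity(pool, tolerance_bp)
  has_a <- grepl("setA", merged$sample_ids)
  has_b <- grepl("setB", merged$sample_ids)
  list(only_a = sum(has_a & !has_b), only_b = sum(!has_a & has_b),
       both = sum(has_a & has_b))
}

#' Between-group correlation of per-gene circle totals
#'
#' Pearson correlation (t-transform p-value, n - 2 df) between per-gene
#' circle totals of two groups over a shared gene universe.
#'
#' @param totals_a,totals_b named numeric vectors of per-gene totals; names
#'   must cover the same gene set.
#' @return list `(r, p, n)`.
#' @export
per_gene_quantity_correlation <- function(totals_a, totals_b) {
  if (!is.null(names(totals_a)) && !is.null(names(totals_b))) {
    if (!setequal(names(totals_a), names(totals_b))) {
      stop("the two groups must share the same gene universe")
    }
    totals_b <- totals_b[names(totals_a)]
  } else if (length(totals_a) != length(totals_b)) {
    stop("per-gene vectors differ in length")
  }
  pearson_correlation(as.numeric(totals_a), as.numeric(totals_b))
}
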