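## Desk-scale junction caller. Detection principle: outward-oriented
## discordant read pairs coarsely localize the circular-DNA interface, then
## soft-clipped (split) reads fix its exact coordinates — a clipped segment
## confirms the junction when it matches the genome sequence entering the
## opposite circle edge. Coverage metrics quantify support for the
## downstream confidence tiers.

#' Caller parameters
#'
#' @param min_structural_reads minimum `n_split + n_discordant` for a call;
#'   the default of 2 encodes the "two independent structural-read variants"
#'   rule (e.g. one split read plus one discordant pair).
#' @param min_split minimum confirming split reads; defaults to 1 because
#'   every confidence tier requires split support, so split-free calls would
#'   be unclassifiable.
#' @param cluster_gap_bp clustering gap for discordant-pair implied
#'   intervals; `NULL` means `insert_mean + 3 * insert_sd` at call time.
#' @param clip_match_min_bp minimum clipped-segment length considered.
#' @param clip_mismatch_max maximum mismatches tolerated when matching a
#'   clipped segment against the opposite edge.
#' @param flank_bp flank-window width for the edge coverage-increase ratios.
#' @return list of class `caller_params`.
#' @export
caller_params <- function(min_structural_reads = 2L, min_split = 1L,
                          cluster_gap_bp = NULL, clip_match_min_bp = 10L,
                          clip_mismatch_max = 1L, flank_bp = 100L) {
  if (min_structural_reads < 1L) stop("min_structural_reads must be >= 1")
  if (min_split < 0L) stop("min_split must be >= 0")
  structure(list(min_structural_reads = as.integer(min_structural_reads),
                 min_split = as.integer(min_split),
                 cluster_gap_bp = cluster_gap_bp,
                 clip_match_min_bp = as.integer(clip_match_min_bp),
                 clip_mismatch_max = as.integer(clip_mismatch_max),
                 flank_bp = as.integer(flank_bp)),
            class = "caller_params")
}

#' Read alignments from a SAM file
#'
#' Thin wrapper over Rsamtools: the SAM is converted to BAM in a temporary
#' directory and scanned; returns a `data.frame` of primary mapped records
#' with 0-based `start`, reference-space `width`, flag-derived orientation
#' fields and the soft-clip structure parsed from the CIGAR.
#'
#' @param path SAM file path.
#' @return `data.frame` of alignment records.
#' @export
read_alignments <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  on.exit(unlink(bam))
  res <- Rsamtools::scanBam(bam, param = Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "cigar", "mrnm", "mpos",
             "seq")))[[1]]
  keep <- !is.na(res$pos) & !bitwAnd(res$flag, 256L) &
    !bitwAnd(res$flag, 2048L)
  flag <- res$flag[keep]
  cigar <- res$cigar[keep]
  ref_width <- GenomicAlignments::cigarWidthAlongReferenceSpace(cigar)
  ops <- GenomicAlignments::explodeCigarOps(cigar)
  lens <- GenomicAlignments::explodeCigarOpLengths(cigar)
  first_op <- vapply(ops, `[`, character(1), 1L)
  last_op <- vapply(ops, function(o) o[length(o)], character(1))
  left_clip <- ifelse(first_op == "S",
                      vapply(lens, `[`, numeric(1), 1L), 0)
  right_clip <- ifelse(last_op == "S",
                       vapply(lens, function(l) l[length(l)], numeric(1)), 0)
  data.frame(
    qname = res$qname[keep],
    flag = flag,
    chrom = as.character(res$rname[keep]),
    start = res$pos[keep] - 1L,            # 0-based
    width = ref_width,
    paired = bitwAnd(flag, 1L) > 0L,
    reverse = bitwAnd(flag, 16L) > 0L,
    mate_reverse = bitwAnd(flag, 32L) > 0L,
    mate_chrom = as.character(res$mrnm[keep]),
    mate_start = ifelse(is.na(res$mpos[keep]), NA_integer_,
                        res$mpos[keep] - 1L),
    cigar = cigar,
    seq = as.character(res$seq[keep]),
    left_clip = left_clip,
    right_clip = right_clip,
    stringsAsFactors = FALSE
  )
}

#' Cluster outward-oriented discordant pairs into candidate intervals
#'
#' A pair is outward-facing when its reverse-strand mate lies upstream of its
#' forward-strand mate on the same chromosome — the orientation produced by a
#' fragment spanning a circle junction. Each pair implies an interval from
#' the reverse mate's start to the forward mate's end; implied intervals
#' whose starts and ends both agree within `cluster_gap_bp` are merged
#' (connected components), and each cluster yields one candidate spanning the
#' outermost implied boundaries.
#'
#' @param aln alignment `data.frame` from [read_alignments()].
#' @param params [caller_params()].
#' @param insert_mean_bp,insert_sd_bp used for the default cluster gap when
#'   `params$cluster_gap_bp` is `NULL`.
#' @return `data.frame` with `chrom`, `start`, `end`, `n_discordant`.
#' @export
find_discordant_clusters <- function(aln, params = caller_params(),
                                     insert_mean_bp = 300,
                                     insert_sd_bp = 30) {
  gap <- params$cluster_gap_bp
  if (is.null(gap)) gap <- insert_mean_bp + 3 * insert_sd_bp
  if (nrow(aln)) {
    per_chrom <- split(aln$start, aln$chrom)
    if (any(vapply(per_chrom, is.unsorted, logical(1)))) {
      stop("alignments must be coordinate-sorted")
    }
  }
  pairs <- aln[aln$paired & !is.na(aln$mate_start), , drop = FALSE]
  if (nrow(pairs) == 0L) {
    if (nrow(aln)) warning("no paired records in alignment stream")
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), n_discordant = integer(),
                      stringsAsFactors = FALSE))
  }
  ## one row per pair: the reverse-strand mate, upstream of a forward mate
  out <- pairs[pairs$reverse & !pairs$mate_reverse &
                 (pairs$mate_chrom == pairs$chrom | pairs$mate_chrom == "=") &
                 pairs$start < pairs$mate_start, , drop = FALSE]
  if (nrow(out) == 0L) {
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), n_discordant = integer(),
                      stringsAsFactors = FALSE))
  }
  implied <- data.frame(chrom = out$chrom, start = out$start,
                        end = out$mate_start + out$width,
                        stringsAsFactors = FALSE)
  clusters <- list()
  for (chrom in unique(implied$chrom)) {
    iv <- implied[implied$chrom == chrom, , drop = FALSE]
    iv <- iv[order(iv$start, iv$end), , drop = FALSE]
    n <- nrow(iv)
    comp <- seq_len(n)
    find <- function(i) { while (comp[i] != i) i <- comp[i]; i }
    for (i in seq_len(n)) {
      j <- i + 1L
      while (j <= n && iv$start[j] - iv$start[i] <= gap) {
        if (abs(iv$end[j] - iv$end[i]) <= gap) {
          comp[find(j)] <- find(i)
        }
        j <- j + 1L
      }
    }
    roots <- vapply(seq_len(n), find, integer(1))
    for (r in unique(roots)) {
      members <- iv[roots == r, , drop = FALSE]
      clusters[[length(clusters) + 1L]] <- data.frame(
        chrom = chrom, start = min(members$start), end = max(members$end),
        n_discordant = nrow(members), stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, clusters)
  res[order(match(res$chrom, unique(aln$chrom)), res$start), , drop = FALSE]
}

#' Refine a candidate interval with soft-clipped reads
#'
#' Each soft-clipped read inside the (margin-padded) candidate proposes one
#' exact junction pair. A read clipped on its right edge fixes the circle
#' end at its alignment end; its clipped segment is the sequence re-entering
#' the circle at the start, so the implied start is where that segment
#' (>= `clip_match_min_bp`, <= `clip_mismatch_max` mismatches) matches the
#' genome near the candidate start. Symmetrically, a left-clipped read fixes
#' the start and its clip locates the end. The (start, end) pair proposed by
#' the most reads wins; ties break to the leftmost start, then leftmost end;
#' matches within a search window also take the leftmost position.
#'
#' @param candidate one-row `data.frame` (`chrom`, `start`, `end`).
#' @param aln alignment `data.frame`.
#' @param genome [Biostrings::DNAStringSet].
#' @param params [caller_params()].
#' @param margin_bp how far around the candidate boundaries to search for
#'   clipped reads and clip matches.
#' @return list `(start, end, n_split)`; the candidate unchanged with
#'   `n_split = 0` when no clip confirms a junction.
#' @export
refine_junction <- function(candidate, aln, genome,
                            params = caller_params(), margin_bp = 400) {
  chrom <- candidate$chrom
  lo <- candidate$start - margin_bp
  hi <- candidate$end + margin_bp
  clen <- length(genome[[chrom]])
  sub <- aln[aln$chrom == chrom & aln$start >= lo &
               (aln$start + aln$width) <= hi &
               (aln$left_clip >= params$clip_match_min_bp |
                  aln$right_clip >= params$clip_match_min_bp), ,
             drop = FALSE]
  fallback <- list(start = candidate$start, end = candidate$end,
                   n_split = 0L)
  if (nrow(sub) == 0L) return(fallback)
  ## leftmost match of `pattern` inside [w_lo, w_hi) (0-based half-open)
  match_in_window <- function(pattern, w_lo, w_hi) {
    w_lo <- max(w_lo, 0); w_hi <- min(w_hi, clen)
    if (w_hi - w_lo < nchar(pattern)) return(NA_integer_)
    hits <- Biostrings::matchPattern(
      pattern, Biostrings::subseq(genome[[chrom]], w_lo + 1L, w_hi),
      max.mismatch = params$clip_mismatch_max)
    if (length(hits) == 0L) return(NA_integer_)
    w_lo + min(Biostrings::start(hits)) - 1L
  }
  props <- list()
  for (k in seq_len(nrow(sub))) {
    r <- sub[k, ]
    if (r$right_clip >= params$clip_match_min_bp) {
      e <- r$start + r$width
      clip_seq <- substr(r$seq, nchar(r$seq) - r$right_clip + 1L,
                         nchar(r$seq))
      s <- match_in_window(clip_seq, candidate$start - margin_bp,
                           candidate$start + margin_bp + nchar(clip_seq))
      if (!is.na(s) && e > s) {
        props[[length(props) + 1L]] <- c(s, e)
      }
    }
    if (r$left_clip >= params$clip_match_min_bp) {
      s <- r$start
      clip_seq <- substr(r$seq, 1L, r$left_clip)
      hit <- match_in_window(clip_seq,
                             candidate$end - margin_bp - nchar(clip_seq),
                             candidate$end + margin_bp)
      if (!is.na(hit)) {
        e <- hit + nchar(clip_seq)
        if (e > s) props[[length(props) + 1L]] <- c(s, e)
      }
    }
  }
  if (!length(props)) return(fallback)
  mat <- do.call(rbind, props)
  key <- paste(mat[, 1], mat[, 2])
  votes <- table(key)
  top <- names(votes)[votes == max(votes)]
  pick <- top[order(as.numeric(sub(" .*", "", top)),
                    as.numeric(sub(".* ", "", top)))][1L]
  parts <- as.numeric(strsplit(pick, " ")[[1]])
  list(start = parts[1], end = parts[2],
       n_split = as.integer(max(votes)))
}

#' Coverage support metrics for a call interval
#'
#' `coverage_fraction` is the fraction of interval bases with depth >= 1.
#' The edge ratios compare mean depth in a `flank_bp` window just outside a
#' boundary with the window just inside:
#' `cov_increase = max(0, 1 - outside / inside)`, clamped to \[0, 1\] and 0
#' when the inside window is uncovered. A clean circle boundary (covered
#' inside, empty outside) scores 1; no depth change scores 0.
#'
#' @param chrom,start,end interval (0-based half-open).
#' @param aln alignment `data.frame`.
#' @param index genome index `data.frame`.
#' @param flank_bp flank window width.
#' @param coverage optional precomputed depth [IRanges::Rle] for `chrom`
#'   (see [chrom_coverage()]); computed from `aln` when `NULL`.
#' @return list `(coverage_fraction, cov_increase_start, cov_increase_end)`.
#' @export
compute_support_metrics <- function(chrom, start, end, aln, index,
                                    flank_bp = 100L, coverage = NULL) {
  chrlen <- index$length[match(chrom, index$chrom)]
  if (is.na(chrlen)) stop("interval on unknown chromosome: ", chrom)
  if (start < 0 || end > chrlen) stop("interval outside chromosome bounds")
  cov <- if (is.null(coverage)) chrom_coverage(aln, chrom, chrlen) else
    coverage
  inside <- IRanges::Views(cov, start + 1L, end)[[1]]
  coverage_fraction <- mean(as.numeric(inside) >= 1)
  win_mean <- function(a, b) {   # 0-based half-open window, clipped
    a <- max(a, 0); b <- min(b, chrlen)
    if (b <= a) return(0)
    mean(as.numeric(IRanges::Views(cov, a + 1L, b)[[1]]))
  }
  edge_ratio <- function(outside, inside_m) {
    if (inside_m <= 0) return(0)
    min(1, max(0, 1 - outside / inside_m))
  }
  w <- flank_bp
  cov_increase_start <- edge_ratio(win_mean(start - w, start),
                                   win_mean(start, min(start + w, end)))
  cov_increase_end <- edge_ratio(win_mean(end, end + w),
                                 win_mean(max(end - w, start), end))
  list(coverage_fraction = coverage_fraction,
       cov_increase_start = cov_increase_start,
       cov_increase_end = cov_increase_end)
}

#' Depth along one chromosome from an alignment table
#' @param aln alignment `data.frame` from [read_alignments()].
#' @param chrom chromosome name.
#' @param chrlen chromosome length (bp).
#' @return an [IRanges::Rle] of per-base depth.
#' @export
chrom_coverage <- function(aln, chrom, chrlen) {
  sub <- aln[aln$chrom == chrom, , drop = FALSE]
  IRanges::coverage(IRanges::IRanges(sub$start + 1L, width = sub$width),
                    width = chrlen)
}

#' Call circles from a SAM file
#'
#' Composition of the caller stages: discordant-pair clustering, split-read
#' junction refinement and coverage metrics. A call is emitted iff
#' `n_split + n_discordant >= min_structural_reads` and
#' `n_split >= min_split`; output is sorted by (chrom, start, end).
#'
#' @param sam SAM path, or an alignment `data.frame` from
#'   [read_alignments()].
#' @param genome [Biostrings::DNAStringSet] of the reference.
#' @param index genome index `data.frame`.
#' @param params [caller_params()].
#' @param sample_id sample id stamped on every call.
#' @param insert_mean_bp,insert_sd_bp fragment geometry for the default
#'   cluster gap.
#' @return A circle-call `data.frame` (see [circle_call_table()]).
#' @export
call_circles <- function(sam, genome, index, params = caller_params(),
                         sample_id = "S1", insert_mean_bp = 300,
                         insert_sd_bp = 30) {
  aln <- if (is.character(sam)) read_alignments(sam) else sam
  cand <- find_discordant_clusters(aln, params, insert_mean_bp,
                                   insert_sd_bp)
  if (nrow(cand) == 0L) return(circle_call_table())
  cov_by_chrom <- lapply(setNames(seq_len(nrow(index)), index$chrom),
                         function(ci) {
                           chrom_coverage(aln, index$chrom[ci],
                                          index$length[ci])
                         })
  calls <- vector("list", nrow(cand))
  for (i in seq_len(nrow(cand))) {
    ref <- refine_junction(cand[i, ], aln, genome, params,
                           margin_bp = insert_mean_bp + 3 * insert_sd_bp)
    if (ref$n_split + cand$n_discordant[i] < params$min_structural_reads ||
        ref$n_split < params$min_split) next
    met <- compute_support_metrics(cand$chrom[i], ref$start, ref$end, aln,
                                   index, params$flank_bp,
                                   coverage = cov_by_chrom[[cand$chrom[i]]])
    calls[[i]] <- circle_call_table(
      chrom = cand$chrom[i], start = ref$start, end = ref$end,
      n_split = ref$n_split, n_discordant = cand$n_discordant[i],
      coverage_fraction = met$coverage_fraction,
      cov_increase_start = met$cov_increase_start,
      cov_increase_end = met$cov_increase_end,
      sample_id = sample_id)
  }
  calls <- calls[!vapply(calls, is.null, logical(1))]
  if (!length(calls)) return(circle_call_table())
  out <- do.call(rbind, calls)
  out <- out[order(match(out$chrom, index$chrom), out$start, out$end), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
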