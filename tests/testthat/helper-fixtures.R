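# Fixtures are built in code: small genomes, hand-written SAM records and
# random-but-seeded call tables.

rand_call_table <- function(n, seed, chroms = c("chr1", "chr2"),
                            sample_ids = "S1") {
  set.seed(seed)
  start <- sample.int(500000, n)
  len <- sample.int(5000, n)
  circle_call_table(
    chrom = sample(chroms, n, replace = TRUE),
    start = start, end = start + len,
    n_split = sample(0:5, n, replace = TRUE),
    n_discordant = sample(0:5, n, replace = TRUE),
    coverage_fraction = round(runif(n), 4),
    cov_increase_start = round(runif(n), 4),
    cov_increase_end = round(runif(n), 4),
    sample_id = sample(sample_ids, n, replace = TRUE))
}

# minimal alignment data.frame accepted by the caller stages
aln_frame <- function(chrom, start, width = 100L, qname = NULL, flag = 0L,
                      paired = FALSE, reverse = FALSE, mate_reverse = FALSE,
                      mate_chrom = NA_character_, mate_start = NA_integer_,
                      seq = "", left_clip = 0, right_clip = 0,
                      cigar = paste0(width, "M")) {
  n <- length(start)
  if (is.null(qname)) qname <- sprintf("r%03d", seq_len(n))
  data.frame(qname = qname, flag = rep_len(flag, n),
             chrom = rep_len(chrom, n), start = start,
             width = rep_len(width, n), paired = rep_len(paired, n),
             reverse = rep_len(reverse, n),
             mate_reverse = rep_len(mate_reverse, n),
             mate_chrom = rep_len(mate_chrom, n),
             mate_start = rep_len(mate_start, n),
             cigar = rep_len(cigar, n), seq = rep_len(seq, n),
             left_clip = rep_len(left_clip, n),
             right_clip = rep_len(right_clip, n), stringsAsFactors = FALSE)
}

# one outward-facing discordant pair (reverse mate upstream)
outward_pair <- function(chrom, rev_start, fwd_start, qname, width = 100L) {
  rbind(
    aln_frame(chrom, rev_start, width, qname = qname, flag = 81L,
              paired = TRUE, reverse = TRUE, mate_reverse = FALSE,
              mate_chrom = chrom, mate_start = fwd_start),
    aln_frame(chrom, fwd_start, width, qname = qname, flag = 161L,
              paired = TRUE, reverse = FALSE, mate_reverse = TRUE,
              mate_chrom = chrom, mate_start = rev_start))
}

sort_aln <- function(aln) {
  aln[order(aln$chrom, aln$start), , drop = FALSE]
}

# small seeded simulation bundle used across caller tests
sim_bundle <- function(seed, n_circles = 10, chrom_lengths = c(400000, 300000),
                       junction_read_depth = 6, background_depth = 3,
                       genes_per_mb = 10, ...) {
  cfg <- sim_config(
    seed = seed,
    chromosomes = data.frame(chrom = paste0("chr",
                                            seq_along(chrom_lengths)),
                             length = chrom_lengths),
    n_circles = n_circles, junction_read_depth = junction_read_depth,
    background_depth = background_depth, genes_per_mb = genes_per_mb, ...)
  gen <- generate_genome(cfg)
  ann <- generate_annotation(gen$index, cfg)
  truth <- plant_circles(gen$index, ann, cfg)
  list(cfg = cfg, genome = gen$genome, index = gen$index, annotation = ann,
       truth = truth)
}

call_key <- function(tab) paste(tab$chrom, tab$start, tab$end)

# independent per-row re-evaluation of the tier rule set
oracle_tier <- function(n_split, coverage, edge_start, edge_end) {
  if (n_split >= 1 && coverage >= 0.80 && edge_start > 0.5 &&
      edge_end > 0.5) return("hconf")
  if (n_split >= 1 && coverage >= 0.80) return("conf")
  if (n_split >= 1) return("lconf")
  NA_character_
}

# direct-formula Pearson oracle (r, then two-sided t transform, n - 2 df)
pearson_r_oracle <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(tstat), n - 2))
}

# brute-force Benjamini-Hochberg step-up
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# exact two-sided rank-sum p by explicit enumeration of labelings
ranksum_oracle <- function(control, case) {
  n1 <- length(case)
  rk <- rank(c(case, control))
  t_obs <- sum(rk[seq_len(n1)])
  sel <- utils::combn(length(rk), n1)
  stat <- colSums(matrix(rk[sel], nrow = n1))
  min(1, 2 * min(mean(stat <= t_obs), mean(stat >= t_obs)))
}

random_metric_calls <- function(n, seed) {
  set.seed(seed)
  # mix free values with exact boundary values to exercise >=/< semantics
  pick <- function(n, boundary) {
    v <- runif(n)
    at <- runif(n) < 0.15
    v[at] <- boundary
    v
  }
  circle_call_table(
    chrom = "chr1", start = seq_len(n) * 10L, end = seq_len(n) * 10L + 5L,
    n_split = sample(0:3, n, replace = TRUE),
    n_discordant = sample(0:3, n, replace = TRUE),
    coverage_fraction = pick(n, 0.80),
    cov_increase_start = pick(n, 0.5),
    cov_increase_end = pick(n, 0.5))
}
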