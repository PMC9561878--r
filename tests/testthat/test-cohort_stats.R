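loci_from <- function(chrom, start, end, sample_id = "S1") {
  merge_locus_identity(circle_call_table(chrom = chrom, start = start,
                                         end = end, n_split = 1,
                                         sample_id = sample_id))
}

test_that("the 100 kb size split is strict and exhaustive", {
  calls <- circle_call_table(chrom = "chr1", start = 0,
                             end = c(358, 99700, 100000, 100001),
                             n_split = 1)
  parts <- partition_by_size(calls)
  expect_equal(parts$eccdna$end, c(358, 99700, 100000))  # 100 kb stays eccDNA
  expect_equal(parts$ecdna$end, 100001)
  expect_equal(nrow(parts$eccdna) + nrow(parts$ecdna), nrow(calls))
  empty <- partition_by_size(circle_call_table())
  expect_equal(nrow(empty$eccdna), 0L)
  expect_equal(nrow(empty$ecdna), 0L)
  for (seed in 1:3) {
    tab <- rand_call_table(200, seed)
    p <- partition_by_size(tab)
    expect_equal(nrow(p$eccdna) + nrow(p$ecdna), 200L)
  }
})

test_that("length peaks: degenerate, tied and error cases", {
  expect_equal(length_histogram(rep(358, 20))$peak_bp, 358)
  expect_equal(length_histogram(c(200, 200, 400, 400))$peak_bp, 200)
  expect_error(length_histogram(numeric(0)), "at least one")
  h <- length_histogram(c(100, 100, 100, 900), bin_width_bp = 1,
                        smoothing_bandwidth_bp = 25)
  expect_equal(h$peak_bp, 100)
  expect_equal(sum(h$counts), 4L)
})

test_that("locus identity merges exact and tolerant coordinate matches", {
  three <- circle_call_table(chrom = "chr1", start = rep(5000, 3),
                             end = rep(5400, 3), n_split = 1,
                             sample_id = c("A", "B", "C"))
  loci <- merge_locus_identity(three, 0)
  expect_equal(nrow(loci), 1L)
  expect_equal(loci$n_samples, 3L)
  shifted <- circle_call_table(chrom = "chr1", start = c(5000, 5005),
                               end = c(5400, 5405), n_split = 1,
                               sample_id = c("A", "B"))
  expect_equal(nrow(merge_locus_identity(shifted, 0)), 2L)
  expect_equal(nrow(merge_locus_identity(shifted, 10)), 1L)
  # representative is the leftmost member
  expect_equal(merge_locus_identity(shifted, 10)$start, 5000)
})

test_that("tolerant merging equals brute-force connected components", {
  bfs_components <- function(tab, tol) {
    n <- nrow(tab)
    adj <- outer(seq_len(n), seq_len(n), function(i, j) {
      tab$chrom[i] == tab$chrom[j] &
        abs(tab$start[i] - tab$start[j]) <= tol &
        abs(tab$end[i] - tab$end[j]) <= tol
    })
    seen <- rep(FALSE, n); n_comp <- 0L
    for (i in seq_len(n)) {
      if (seen[i]) next
      n_comp <- n_comp + 1L
      queue <- i
      while (length(queue)) {
        v <- queue[[1]]; queue <- queue[-1]
        if (seen[v]) next
        seen[v] <- TRUE
        queue <- c(queue, which(adj[v, ] & !seen))
      }
    }
    n_comp
  }
  for (seed in 1:10) {
    set.seed(seed)
    n <- 40
    start <- sample(1:300, n, replace = TRUE) * 7
    tab <- circle_call_table(chrom = sample(c("c1", "c2"), n, TRUE),
                             start = start, end = start + 400,
                             n_split = 1,
                             sample_id = sample(c("A", "B"), n, TRUE))
    for (tol in c(0, 5, 20)) {
      expect_equal(nrow(merge_locus_identity(tab, tol)),
                   bfs_components(tab, tol))
    }
  }
})

test_that("the consistency rule keeps loci seen in >= 2 group samples", {
  man <- data.frame(sample_id = c("A1", "A2", "A3", "C1", "C2"),
                    group = c("AIONFH", "AIONFH", "AIONFH", "control",
                              "control"), path = NA)
  calls <- circle_call_table(
    chrom = "chr1",
    start = c(100, 100, 900, 2000, 2000, 2000),
    end = c(500, 500, 1300, 2400, 2400, 2400), n_split = 1,
    sample_id = c("A1", "A2", "A3", "A1", "C1", "C2"))
  loci <- merge_locus_identity(calls)
  kept_a <- consistency_filter(loci, man, "AIONFH", 2)
  expect_equal(kept_a$start, 100)            # locus 900 in 1 sample: dropped
  kept_c <- consistency_filter(loci, man, "control", 2)
  expect_equal(kept_c$start, 2000)
  all_a <- consistency_filter(loci, man, "AIONFH", 1)
  expect_equal(nrow(all_a), 3L)              # min_samples = 1 keeps all seen
  expect_error(consistency_filter(loci, man, "case"), "unknown")
})

test_that("overlap counts satisfy the Venn identities", {
  a <- loci_from("chr1", c(100, 900, 2000), c(500, 1300, 2400))
  b <- loci_from("chr1", 900, 1300)
  v <- venn_counts(a, b)
  expect_equal(v, list(only_a = 2L, only_b = 0L, both = 1L))
  d1 <- loci_from("chr1", c(1, 1000, 2000) * 10, c(5, 1004, 2004) * 10)
  d2 <- loci_from("chr2", c(1, 1000, 2000, 3000) * 10,
                  c(5, 1004, 2004, 3004) * 10)
  expect_equal(venn_counts(d1, d2), list(only_a = 3L, only_b = 4L,
                                         both = 0L))
  expect_equal(venn_counts(a, a), list(only_a = 0L, only_b = 0L,
                                       both = 3L))
})

test_that("per-gene totals correlate exactly as the direct formula says", {
  x <- c(1, 5, 9, 2)
  expect_equal(per_gene_quantity_correlation(x, x)$r, 1.0)
  expect_equal(per_gene_quantity_correlation(c(1, 2, 3), c(3, 2, 1))$r, -1.0)
  set.seed(123)
  a <- setNames(rpois(100, 6), paste0("g", 1:100))
  b <- setNames(rpois(100, 6) + a, paste0("g", 1:100))
  got <- per_gene_quantity_correlation(a, b)
  want <- pearson_r_oracle(as.numeric(a), as.numeric(b))
  expect_equal(got$r, want$r, tolerance = 1e-12)
  expect_equal(got$p, want$p, tolerance = 1e-12)
  expect_error(per_gene_quantity_correlation(a, b[1:50]), "gene universe")
  expect_error(per_gene_quantity_correlation(c(1, 1, 1), c(1, 2, 3)),
               "constant")
})
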