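test_that("concordant inward pairs never seed candidates", {
  aln <- sort_aln(rbind(
    aln_frame("chr1", 1000, qname = "p1", flag = 99L, paired = TRUE,
              reverse = FALSE, mate_reverse = TRUE, mate_chrom = "chr1",
              mate_start = 1200),
    aln_frame("chr1", 1200, qname = "p1", flag = 147L, paired = TRUE,
              reverse = TRUE, mate_reverse = FALSE, mate_chrom = "chr1",
              mate_start = 1000)))
  cand <- find_discordant_clusters(aln)
  expect_equal(nrow(cand), 0L)
})

test_that("outward pairs cluster into one candidate spanning the junction", {
  aln <- sort_aln(rbind(
    outward_pair("chr1", 1000, 1900, "d1"),
    outward_pair("chr1", 1030, 1880, "d2"),
    outward_pair("chr1", 1010, 1895, "d3")))
  cand <- find_discordant_clusters(aln)
  expect_equal(nrow(cand), 1L)
  expect_equal(cand$n_discordant, 3L)
  expect_equal(cand$start, 1000)       # outermost implied boundaries
  expect_equal(cand$end, 2000)         # 1900 + 100 bp read
})

test_that("pairs separated beyond the gap form separate clusters", {
  aln <- sort_aln(rbind(
    outward_pair("chr1", 1000, 1900, "d1"),
    outward_pair("chr1", 11000, 11900, "d2")))
  cand <- find_discordant_clusters(aln, caller_params(cluster_gap_bp = 500))
  expect_equal(nrow(cand), 2L)
})

test_that("unsorted alignments are rejected; unpaired streams warn", {
  aln <- rbind(outward_pair("chr1", 5000, 5400, "d1"),
               outward_pair("chr1", 1000, 1400, "d2"))
  expect_error(find_discordant_clusters(aln), "coordinate-sorted")
  solo <- aln_frame("chr1", c(100, 300), paired = FALSE)
  expect_warning(cand <- find_discordant_clusters(solo), "no paired")
  expect_equal(nrow(cand), 0L)
})

test_that("split reads refine a candidate to the exact junction", {
  b <- sim_bundle(13, n_circles = 1, chrom_lengths = 100000,
                  junction_read_depth = 6, background_depth = 2)
  crc <- b$truth$circles[1, ]
  recs <- simulate_reads(b$truth, b$genome, b$cfg, "S1")
  sam <- withr::local_tempfile(fileext = ".sam")
  write_sam(recs, b$index, sam)
  aln <- read_alignments(sam)
  cand <- find_discordant_clusters(aln)
  expect_equal(nrow(cand), 1L)
  ref <- refine_junction(cand[1, ], aln, b$genome)
  expect_equal(ref$start, crc$start)
  expect_equal(ref$end, crc$end)
  expect_gte(ref$n_split, 1L)
})

test_that("clips that match nowhere leave the candidate unchanged", {
  b <- sim_bundle(14, n_circles = 1, chrom_lengths = 50000,
                  background_depth = 0)
  cand <- data.frame(chrom = "chr1", start = 2000, end = 3000)
  junk <- aln_frame("chr1", 2500, width = 80L, qname = "sc1",
                    cigar = "80M20S", right_clip = 20,
                    seq = paste(rep("A", 100), collapse = ""))
  junk2 <- aln_frame("chr1", 2400, width = 80L, qname = "sc2",
                     cigar = "20S80M", left_clip = 20,
                     seq = paste(rep("A", 100), collapse = ""))
  ref <- refine_junction(cand, sort_aln(rbind(junk, junk2)), b$genome)
  expect_equal(ref$start, 2000)
  expect_equal(ref$end, 3000)
  expect_equal(ref$n_split, 0L)
})

test_that("support metrics match closed forms on step-function depth", {
  idx <- genome_index("chr1", 10000)
  inside <- aln_frame("chr1", rep(2000, 10), width = 1000L)
  m <- compute_support_metrics("chr1", 2000, 3000, inside, idx)
  expect_equal(m$coverage_fraction, 1)
  expect_equal(m$cov_increase_start, 1)
  expect_equal(m$cov_increase_end, 1)
  flat <- aln_frame("chr1", rep(0, 10), width = 10000L)
  m2 <- compute_support_metrics("chr1", 2000, 3000, flat, idx)
  expect_equal(m2$cov_increase_start, 0)
  expect_equal(m2$cov_increase_end, 0)
  none <- aln_frame("chr1", integer(0))
  m3 <- compute_support_metrics("chr1", 2000, 3000, none, idx)
  expect_equal(m3$coverage_fraction, 0)
  expect_equal(m3$cov_increase_start, 0)
  expect_error(compute_support_metrics("chr1", 9000, 11000, none, idx),
               "outside chromosome")
  expect_error(compute_support_metrics("chrX", 0, 10, none, idx),
               "unknown chromosome")
})

test_that("the two-structural-reads rule decides emission", {
  b <- sim_bundle(15, n_circles = 1, chrom_lengths = 80000,
                  junction_read_depth = 2, background_depth = 0)
  recs <- simulate_reads(b$truth, b$genome, b$cfg, "S1")
  expect_equal(sum(grepl("^split_", recs$qname)), 1L)
  expect_equal(sum(grepl("^disc_", recs$qname)), 2L)  # one pair
  sam <- withr::local_tempfile(fileext = ".sam")
  write_sam(recs, b$index, sam)
  calls <- call_circles(sam, b$genome, b$index, sample_id = "S1")
  expect_equal(nrow(calls), 1L)    # 1 split + 1 discordant = 2 >= 2
  # drop the discordant pair: 1 split + 0 discordant fails the threshold
  solo <- recs[grepl("^split_", recs$qname), ]
  write_sam(solo, b$index, sam)
  calls0 <- suppressWarnings(
    call_circles(sam, b$genome, b$index, sample_id = "S1"))
  expect_equal(nrow(calls0), 0L)
})

test_that("recovery on clean reads: high recall, exact coordinates", {
  for (seed in 1:5) {
    b <- sim_bundle(seed + 100, n_circles = 10,
                    chrom_lengths = c(400000, 300000),
                    junction_read_depth = 6, background_depth = 3)
    recs <- suppressWarnings(simulate_reads(b$truth, b$genome, b$cfg, "S1"))
    sam <- withr::local_tempfile(fileext = ".sam")
    write_sam(recs, b$index, sam)
    calls <- call_circles(sam, b$genome, b$index, sample_id = "S1")
    expect_gte(mean(call_key(b$truth$circles) %in% call_key(calls)), 0.9)
    expect_true(all(call_key(calls) %in% call_key(b$truth$circles)))
    expect_true(all(calls$n_split + calls$n_discordant >= 2))
  }
})

test_that("raising min_structural_reads never increases the call count", {
  b <- sim_bundle(16, n_circles = 8, junction_read_depth = 5,
                  background_depth = 2)
  recs <- simulate_reads(b$truth, b$genome, b$cfg, "S1")
  sam <- withr::local_tempfile(fileext = ".sam")
  write_sam(recs, b$index, sam)
  aln <- read_alignments(sam)
  n_prev <- Inf
  for (thr in c(2, 4, 6, 8)) {
    calls <- call_circles(aln, b$genome, b$index,
                          caller_params(min_structural_reads = thr))
    expect_lte(nrow(calls), n_prev)
    expect_true(all(calls$n_split + calls$n_discordant >= thr))
    n_prev <- nrow(calls)
  }
})
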