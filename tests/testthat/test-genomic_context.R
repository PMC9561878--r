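context_fixture <- function() {
  # gA: + strand gene at [10000,14000) with exons [10000,11000)+[13000,14000)
  # gB: - strand gene at [30000,34000), single exon covering the body
  genes <- data.frame(gene_id = c("gA", "gB"), chrom = "chr1",
                      start = c(10000, 30000), end = c(14000, 34000),
                      strand = c("+", "-"), stringsAsFactors = FALSE)
  exons <- data.frame(gene_id = c("gA", "gA", "gB"),
                      start = c(10000, 13000, 30000),
                      end = c(11000, 14000, 34000))
  gene_models(genes, exons)
}

ctx_call <- function(start, end, chrom = "chr1") {
  circle_call_table(chrom = chrom, start = start, end = end, n_split = 1)
}

test_that("region attribution follows the fixed precedence", {
  models <- context_fixture()
  expect_equal(as.character(classify_region(ctx_call(10100, 10200), models)),
               "exon")
  # overlaps intron of gA and (if gB were nearer) a flank: intron wins
  expect_equal(as.character(classify_region(ctx_call(11500, 11600), models)),
               "intron")
  # spans exon boundary: exon beats intron
  expect_equal(as.character(classify_region(ctx_call(10900, 11100), models)),
               "exon")
  # + strand: up2k is 5' of the body; - strand: up2k is right of the body
  expect_equal(as.character(classify_region(ctx_call(9000, 9100), models)),
               "gene_up2k")
  expect_equal(as.character(classify_region(ctx_call(14100, 14200), models)),
               "gene_down2k")
  expect_equal(as.character(classify_region(ctx_call(34100, 34200), models)),
               "gene_up2k")
  expect_equal(as.character(classify_region(ctx_call(29000, 29100), models)),
               "gene_down2k")
  expect_equal(as.character(classify_region(ctx_call(500000, 500100),
                                            models)), "intergenic")
  expect_equal(as.character(classify_region(ctx_call(100, 200, "chrEmpty"),
                                            models)), "intergenic")
})

test_that("region counts conserve the number of calls", {
  models <- context_fixture()
  calls <- rbind(ctx_call(10100, 10200), ctx_call(11500, 11600),
                 ctx_call(9000, 9100), ctx_call(14100, 14200),
                 ctx_call(70000, 70500))
  dist <- region_distribution(calls, models)
  expect_equal(unname(dist),
               c(exon = 1L, intron = 1L, gene_up2k = 1L, gene_down2k = 1L,
                 intergenic = 1L), ignore_attr = TRUE)
  expect_equal(sum(dist), nrow(calls))
  expect_equal(sum(region_distribution(circle_call_table(), models)), 0L)
})

test_that("per-gene counting increments every overlapped gene", {
  models <- context_fixture()
  spanning <- ctx_call(13900, 30100)   # touches gA and gB
  counts <- count_per_gene(spanning, models)
  expect_equal(unname(counts["gA"]), 1L)
  expect_equal(unname(counts["gB"]), 1L)
  calls <- rbind(ctx_call(10100, 10200), ctx_call(11000, 12000),
                 ctx_call(13500, 13600), ctx_call(70000, 70100))
  counts2 <- count_per_gene(calls, models)
  expect_equal(unname(counts2["gA"]), 3L)
  expect_equal(unname(counts2["gB"]), 0L)
  expect_equal(unname(count_per_gene(circle_call_table(), models)),
               c(0L, 0L))
  # containment mode drops partially overlapping calls
  expect_equal(unname(count_per_gene(spanning, models,
                                     mode = "containment")), c(0L, 0L))
  expect_error(count_per_gene(calls, models, mode = "bogus"))
})

test_that("per-chromosome densities include empty chromosomes", {
  idx <- genome_index(c("chr1", "chr2"), c(2e6, 1e6))
  models <- context_fixture()
  calls <- ctx_call(rep(1000, 10) + (1:10) * 2000, rep(1500, 10) +
                      (1:10) * 2000)
  dens <- density_per_chromosome(calls, idx, models)
  expect_equal(dens$n_circles, c(10L, 0L))
  expect_equal(dens$circles_per_mb, c(5, 0))
  expect_equal(dens$genes_per_mb, c(2 / 2, 0))
  expect_error(density_per_chromosome(ctx_call(1, 2, "chrX"), idx, models),
               "absent from genome index")
})

test_that("density correlation matches the direct Pearson formula", {
  d <- data.frame(circles_per_mb = c(2, 4, 6, 8, 10),
                  genes_per_mb = c(1, 2, 3, 4, 5))
  expect_equal(correlate_density(d)$r, 1.0)
  d2 <- data.frame(circles_per_mb = c(1, 2, 3, 4),
                   genes_per_mb = c(4, 3, 2, 1))
  expect_equal(correlate_density(d2)$r, -1.0)
  expect_error(correlate_density(data.frame(circles_per_mb = 1:4,
                                            genes_per_mb = rep(2, 4))),
               "constant")
  set.seed(99)
  x <- runif(24); y <- 0.4 * x + runif(24)
  got <- pearson_r_oracle(x, y)
  res <- correlate_density(data.frame(circles_per_mb = x,
                                      genes_per_mb = y))
  expect_equal(res$r, got$r, tolerance = 1e-12)
  expect_equal(res$p, got$p, tolerance = 1e-12)
  expect_equal(res$n, 24L)
})

test_that("window binning counts every call in each window it overlaps", {
  idx <- genome_index("chr1", 120000)
  calls <- rbind(ctx_call(10, 500), ctx_call(49900, 50100),
                 ctx_call(110000, 119000))
  win <- window_density(calls, idx, window_bp = 50000)
  expect_equal(nrow(win), 3L)
  expect_equal(win$n_circles, c(2L, 1L, 1L))   # straddler counted twice
  expect_equal(win$end[3], 120000)
})
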