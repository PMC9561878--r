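mini_manifest <- function(n_case = 3, n_control = 3) {
  data.frame(sample_id = c(sprintf("A%d", seq_len(n_case)),
                           sprintf("C%d", seq_len(n_control))),
             group = c(rep("AIONFH", n_case), rep("control", n_control)),
             path = NA)
}

test_that("group means average (optionally normalized) sample columns", {
  man <- mini_manifest()
  mat <- rbind(g1 = c(10, 20, 30, 1, 2, 3), g2 = rep(0, 6))
  colnames(mat) <- man$sample_id
  cfg <- differential_config(normalization = "none")
  gm <- group_means(mat, man, cfg)
  expect_equal(gm$mean_case[1], 20)
  expect_equal(gm$mean_control[1], 2)
  expect_equal(gm$mean_case[2], 0)
  expect_equal(gm$mean_control[2], 0)
  # total-count scaling: doubling one sample's counts only rescales the
  # cohort target, so every normalized entry changes by one common factor
  mat1 <- mat + 1
  mat2 <- mat1; mat2[, "A1"] <- mat2[, "A1"] * 2
  ratio <- normalize_total_count(mat2) / normalize_total_count(mat1)
  expect_equal(max(ratio), min(ratio))
  expect_error(group_means(mat, man[man$group == "AIONFH", ], cfg),
               "non-empty")
})

test_that("pseudocount log2 fold change reproduces the published rows", {
  # printed (control, case) means -> printed log2(fc)
  expect_equal(compute_log2fc(34.36, 610.1686), 4.150406, tolerance = 1e-3)
  expect_equal(compute_log2fc(642.4114, 0), -19.2931, tolerance = 1e-3)
  expect_equal(compute_log2fc(2.771429, 445.0943), 7.327337,
               tolerance = 1e-3)
  expect_equal(compute_log2fc(5.542857, 445.0943), 6.327337,
               tolerance = 1e-3)
  expect_equal(compute_log2fc(896.1243, 56.55429), -3.98599,
               tolerance = 1e-3)
  # doubling the control mean costs exactly one log2 unit
  expect_equal(compute_log2fc(2.771429, 445.0943) -
                 compute_log2fc(5.542857, 445.0943), 1, tolerance = 1e-6)
})

test_that("the pseudocount triggers only at exactly zero", {
  expect_equal(compute_log2fc(7, 7), 0)
  expect_true(is.na(compute_log2fc(0, 0)))
  eps <- 1e-9
  jump <- abs(compute_log2fc(5, eps) - compute_log2fc(5, 2 * eps))
  expect_equal(jump, 1, tolerance = 1e-6)   # continuous away from zero
  expect_equal(compute_log2fc(0, 32), log2(32 / 0.001))
  expect_error(compute_log2fc(-1, 5), "non-negative")
})

test_that("swapping the group roles negates every log2fc", {
  set.seed(4)
  a <- c(0, runif(20, 0, 100))
  b <- c(5, runif(20, 0, 100))
  expect_equal(compute_log2fc(a, b), -compute_log2fc(b, a))
})

test_that("the exact rank-sum enumerates all labelings", {
  sep <- test_gene(1:7, 101:107, differential_config())
  expect_equal(sep, 2 / choose(14, 7), tolerance = 1e-12)
  same <- test_gene(rep(3, 5), rep(3, 5), differential_config())
  expect_equal(same, 1)
  expect_error(test_gene(1, 1:5), "at least 2")
  set.seed(8)
  x <- rnorm(5); y <- rnorm(5) + 1
  expect_equal(test_gene(x, y, differential_config()),
               ranksum_oracle(x, y), tolerance = 1e-12)
})

test_that("permutation p sits within Monte-Carlo error of the exact p", {
  set.seed(31)
  x <- rnorm(5); y <- rnorm(5) + 1.2
  exact <- ranksum_oracle(x, y)
  perm <- test_gene(x, y, differential_config(test = "permutation",
                                              n_permutations = 20000,
                                              perm_seed = 12))
  se <- 2 * sqrt(exact / 2 * (1 - exact / 2) / 20000)
  expect_lt(abs(perm - exact), 3 * se + 1e-9)
})

test_that("BH correction equals the brute-force step-up", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_error(bh_fdr(c(0.1, 1.2)), "\\[0, 1\\]")
  for (seed in 1:5) {
    set.seed(seed)
    p <- runif(50)
    expect_equal(bh_fdr(p), bh_oracle(p), tolerance = 1e-12)
  }
})

test_that("the significance filter is strict at both boundaries", {
  rec <- data.frame(gene_id = c("a", "b", "c", "d"),
                    log2fc = c(2, -1.5, 1.0, 3),
                    p_value = c(0.01, 0.04, 0.01, 0.05))
  sig <- significant_genes(rec, differential_config())
  expect_equal(sig$table$gene_id, c("a", "b"))  # c: lfc == 1; d: p == 0.05
  expect_equal(sig$n_up, 1L)
  expect_equal(sig$n_down, 1L)
})

test_that("planted abundance ratios are recovered at default thresholds", {
  hits <- 0L; total <- 0L
  for (seed in 1:5) {
    # small-circle background only: on desk-scale chromosomes the kb-scale
    # tail would blanket whole gene neighborhoods and mask any planted
    # per-gene effect. Background presence is equal across groups, so the
    # cohort has no library-size difference and scaling is off; the planted
    # ratio (12 vs 1.5 over a ~2-per-gene background) stays >= 4
    b <- sim_bundle(seed + 300, n_circles = 300,
                    chrom_lengths = c(600000, 500000), genes_per_mb = 40,
                    tail_fraction = 0, ecdna_fraction = 0)
    man <- mini_manifest(7, 7)
    de_ids <- head(b$annotation$genes$gene_id, 5)
    de <- data.frame(gene_id = de_ids, rate_case = 12, rate_control = 1.5)
    calls <- simulate_cohort_calls(b$truth, man, b$cfg,
                                   presence_prob = c(AIONFH = 0.55,
                                                     control = 0.55),
                                   de = de)
    mat <- gene_count_matrix(calls, b$annotation)
    res <- run_differential(mat, man,
                            differential_config(normalization = "none"))
    sig <- significant_genes(res)
    hits <- hits + sum(de_ids %in% sig$table$gene_id)
    total <- total + length(de_ids)
  }
  expect_gte(hits / total, 0.8)
})

test_that("the full differential table is internally consistent", {
  b <- sim_bundle(55, n_circles = 20, genes_per_mb = 15)
  man <- mini_manifest(4, 4)
  calls <- simulate_cohort_calls(b$truth, man, b$cfg)
  mat <- gene_count_matrix(calls, b$annotation)
  res <- run_differential(mat, man)
  expect_equal(nrow(res), nrow(mat))
  expect_true(all(res$fdr >= res$p_value - 1e-12))
  expect_true(all(res$significant ==
                    (!is.na(res$log2fc) & res$p_value < 0.05 &
                       abs(res$log2fc) > 1)))
  expect_true(all(res$direction[res$log2fc > 0] == "up", na.rm = TRUE))
})
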