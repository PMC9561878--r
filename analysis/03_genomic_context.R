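#!/usr/bin/env Rscript
# Stage 3: genomic context of the pooled calls.
#
# Attributes each call to exon/intron/gene_up2k/gene_down2k/intergenic
# (precedence order, 2 kb strand-aware flanks), computes per-chromosome
# circle density against gene density with a Pearson test per group, and a
# 50 kb window scan.

library(eccatlas)

data_dir <- file.path("results", "data")
calls_dir <- file.path("results", "calls")
out <- file.path("results", "context")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

manifest <- read_manifest(file.path(data_dir, "manifest.tsv"))
index <- read_genome_index(file.path(data_dir, "genome_index.tsv"))
models <- read_gene_models(file.path(data_dir, "genes.gff3"), "gff3")
pooled <- do.call(rbind, lapply(manifest$sample_id, function(s) {
  read_circle_table(file.path(calls_dir, paste0("calls_", s, ".tsv")),
                    "native")
}))

regions <- region_distribution(pooled, models, index = index)
write.table(data.frame(region = names(regions), n_calls = regions),
            file.path(out, "region_distribution.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("genic-region origin of pooled calls:\n")
print(regions)

corr_lines <- character()
for (grp in c("AIONFH", "control")) {
  ids <- manifest$sample_id[manifest$group == grp]
  sub <- pooled[pooled$sample_id %in% ids, ]
  dens <- density_per_chromosome(sub, index, models)
  write.table(dens, file.path(out, paste0("density_", grp, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cr <- correlate_density(dens)
  corr_lines <- c(corr_lines,
                  sprintf("%s\t%.6f\t%.6f\t%d", grp, cr$r, cr$p, cr$n))
  cat(sprintf("%s: circles/Mb vs genes/Mb r = %.3f (p = %.4f, n = %d)\n",
              grp, cr$r, cr$p, cr$n))
}
writeLines(c("group\tr\tp\tn", corr_lines),
           file.path(out, "density_correlation.tsv"))

win <- window_density(pooled, index, window_bp = 50000)
write.table(win, file.path(out, "window_density_50kb.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("50 kb scan: %d windows, max %d calls in one window\n",
            nrow(win), max(win$n_circles)))
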