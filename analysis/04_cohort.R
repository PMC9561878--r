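#!/usr/bin/env Rscript
# Stage 4: cohort-level statistics.
#
# Splits calls at the 100 kb eccDNA/ecDNA boundary, locates the per-group
# length-distribution peak (1 bp bins, 25 bp Gaussian smoothing), merges
# calls into cohort loci by exact coordinates, applies the consistency rule
# (>= 2 samples of a group) and counts the group overlap.

library(eccatlas)

data_dir <- file.path("results", "data")
calls_dir <- file.path("results", "calls")
out <- file.path("results", "cohort")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

manifest <- read_manifest(file.path(data_dir, "manifest.tsv"))
pooled <- do.call(rbind, lapply(manifest$sample_id, function(s) {
  read_circle_table(file.path(calls_dir, paste0("calls_", s, ".tsv")),
                    "native")
}))

parts <- partition_by_size(pooled)
cat(sprintf("size classes: %d eccDNA (<= 100 kb), %d ecDNA (> 100 kb)\n",
            nrow(parts$eccdna), nrow(parts$ecdna)))

peaks <- character()
for (grp in c("AIONFH", "control")) {
  ids <- manifest$sample_id[manifest$group == grp]
  lens <- parts$eccdna$length[parts$eccdna$sample_id %in% ids]
  h <- length_histogram(lens)
  peaks <- c(peaks, sprintf("%s\t%d\t%d", grp, h$peak_bp, length(lens)))
  cat(sprintf("%s length peak: %d bp over %d eccDNA calls\n", grp,
              h$peak_bp, length(lens)))
}
writeLines(c("group\tpeak_bp\tn_calls", peaks),
           file.path(out, "length_peaks.tsv"))

loci <- merge_locus_identity(pooled, tolerance_bp = 0)
write.table(loci, file.path(out, "loci.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
cons_a <- consistency_filter(loci, manifest, "AIONFH", 2)
cons_c <- consistency_filter(loci, manifest, "control", 2)
write.table(cons_a, file.path(out, "consistent_AIONFH.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(cons_c, file.path(out, "consistent_control.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
v <- venn_counts(cons_a, cons_c)
writeLines(c("only_AIONFH\tonly_control\tboth",
             sprintf("%d\t%d\t%d", v$only_a, v$only_b, v$both)),
           file.path(out, "venn.tsv"))
cat(sprintf("cohort loci: %d; consistent: %d AIONFH, %d control;\n",
            nrow(loci), nrow(cons_a), nrow(cons_c)))
cat(sprintf("overlap: %d only-AIONFH, %d only-control, %d shared\n",
            v$only_a, v$only_b, v$both))
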