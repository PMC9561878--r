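#!/usr/bin/env Rscript
# Stage 1: simulate the study cohort.
#
# Two groups of 7 femoral-head samples (AIONFH cases vs femoral-neck-fracture
# controls) over a 4.2 Mb four-chromosome genome. A master set of 60 circle
# loci is planted with gene-density coupling on; each sample carries a locus
# with a group-specific presence probability (cases form fewer circles, as
# reported for this disease), and junction-supporting reads are written as
# coordinate-sorted SAM.

library(eccatlas)

out <- file.path("results", "data")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

config <- default_pipeline_config(seed = 1L, out_dir = out)
stopifnot(length(validate_config(config)) == 0L)

sim <- config$simulate
cfg <- sim_config(
  seed = config$seed,
  chromosomes = data.frame(chrom = names(sim$chromosomes),
                           length = unlist(sim$chromosomes)),
  genes_per_mb = sim$genes_per_mb, n_circles = sim$n_circles,
  background_depth = sim$background_depth,
  junction_read_depth = sim$junction_read_depth,
  gene_density_coupling = sim$gene_density_coupling)

gen <- generate_genome(cfg)
annotation <- generate_annotation(gen$index, cfg)
truth <- plant_circles(gen$index, annotation, cfg)

write_genome_index(gen$index, file.path(out, "genome_index.tsv"))
write_gene_models_gff3(annotation, file.path(out, "genes.gff3"))
write_truth(truth, file.path(out, "truth.tsv"))
Biostrings::writeXStringSet(gen$genome, file.path(out, "genome.fa"))

manifest <- data.frame(
  sample_id = c(sprintf("A%02d", seq_len(sim$n_case)),
                sprintf("C%02d", seq_len(sim$n_control))),
  group = c(rep("AIONFH", sim$n_case), rep("control", sim$n_control)),
  path = NA_character_)

for (si in seq_len(nrow(manifest))) {
  sid <- manifest$sample_id[si]
  pp <- sim$presence_prob[[manifest$group[si]]]
  present <- circle_presence(truth, cfg, si, pp)
  recs <- suppressWarnings(
    simulate_reads(truth, gen$genome, cfg, sample_id = sid,
                   circles = truth$circles[present, , drop = FALSE]))
  manifest$path[si] <- paste0("sample_", sid, ".sam")
  write_sam(recs, gen$index, file.path(out, manifest$path[si]))
  cat(sprintf("%s (%s): %d loci present, %d alignment records\n",
              sid, manifest$group[si], sum(present), nrow(recs)))
}
write_manifest(manifest, file.path(out, "manifest.tsv"))

cat(sprintf("\nplanted %d circles (%d genes annotated); cohort written to %s\n",
            nrow(truth$circles), nrow(annotation$genes), out))
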