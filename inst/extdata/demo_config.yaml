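seed: 1.0
out_dir: results/pipeline_demo
simulate:
  chromosomes:
    chr1: 1500000.0
    chr2: 1200000.0
    chr3: 900000.0
    chr4: 600000.0
  genes_per_mb: 12.0
  n_circles: 60.0
  junction_read_depth: 6.0
  background_depth: 3.0
  gene_density_coupling: yes
  n_case: 7.0
  n_control: 7.0
  presence_prob:
    AIONFH: 0.45
    control: 0.6
caller:
  min_structural_reads: 2.0
  min_split: 1.0
confidence:
  min_coverage_fraction: 0.8
  min_edge_ratio: 0.5
context:
  flank_bp: 2000.0
  window_bp: 50000.0
cohort:
  min_samples: 2.0
  tolerance_bp: 0.0
  size_cutoff_bp: 100000.0
  smoothing_bandwidth_bp: 25.0
differential:
  pseudocount: 0.001
  alpha: 0.05
  min_abs_log2fc: 1.0
  normalization: total
  test: ranksum
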