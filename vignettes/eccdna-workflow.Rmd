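---
title: "Methods: junction-evidence eccDNA calling and cohort analysis"
author: "eccatlas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: junction-evidence eccDNA calling and cohort analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## Scope

`eccatlas` re-implements, as a tested workflow, the computational side of a
Circle-seq study of extrachromosomal circular DNA (eccDNA) in alcohol-induced
osteonecrosis of the femoral head (AIONFH, 7 cases) versus femoral-neck
fracture tissue (7 controls): junction-evidence circle calling, a three-tier
confidence classification, genomic characterization, cross-sample cohort
logic, and a per-gene differential analysis with a zero-replacement
pseudocount. Everything runs on synthetic Circle-seq-like data generated by
the package plus the published table of 25 significant exon-region genes,
which is bundled as a plain-text fixture; the study's restricted sequencing
data are not used.

The repository is organised as an analysis workflow: numbered drivers under
`analysis/` narrate the stages and write tables under `results/`, while every
computation lives in package functions so the tests and the acceptance script
exercise the same code. The drivers together with `run_pipeline()` /
`validate_config()` are the workflow's operational surface; no separate shell
wrapper is provided.

## Detection model

A circular element excised from locus `[s, e)` produces two alignment
signatures against the linear reference:

* **Outward-oriented discordant pairs.** A fragment spanning the circle
  junction aligns with its reverse-strand mate near `s` and its
  forward-strand mate near `e` — the opposite of the inward orientation of
  linear-library pairs. These coarsely localize the interface:
  `find_discordant_clusters()` groups pairs whose implied intervals agree
  within `cluster_gap_bp` (default `insert_mean + 3*insert_sd`) into one
  candidate spanning the outermost implied boundaries.
* **Soft-clipped split reads.** A read crossing the junction aligns partly at
  one edge; the clipped remainder is the sequence entering the opposite edge.
  `refine_junction()` lets each clipped read (clip >= 10 bp, <= 1 mismatch)
  propose an exact `(s, e)` pair — the aligned edge fixes one boundary, the
  leftmost match of the clip near the other candidate boundary fixes the
  second — and takes the pair with most supporting reads. Ties break to the
  leftmost start, then leftmost end, so refinement is deterministic.

A call is emitted only when `n_split + n_discordant >= 2` (at least two
independent structural-read variants, e.g. one split read and one discordant
pair) and `n_split >= 1`. The split-read floor is not redundant: every
confidence tier requires split support, so split-free calls would be
unclassifiable. This is a deliberate re-implementation of the detection
principle only — no probabilistic realignment, no decomposition of
overlapping circles, no cross-chromosome chimeras.

Coverage support is summarized by `compute_support_metrics()`:
`coverage_fraction` is the fraction of interval bases with depth >= 1, and
each boundary gets a coverage-increase ratio
`max(0, 1 - mean depth in the 100 bp flank outside / mean depth in the
100 bp just inside)`, clamped to [0, 1]. A clean circle boundary (covered
inside, empty outside) scores 1; no depth change scores 0.

## Confidence tiers

Calls are ranked `lconf < conf < hconf`:

| tier  | rule |
|-------|------|
| lconf | split reads >= 1 |
| conf  | lconf **and** interval coverage >= 80% |
| hconf | conf **and** both boundary coverage-increase ratios > 0.5 |

Boundary semantics follow the rule set's wording: coverage is compared
inclusively (>= 0.80), the edge ratios strictly (> 0.5). The hconf depth
criterion ("copy number more than twice the surrounding average") is
operationalized through the edge ratios, since an interior depth at least
twice the flank depth is exactly an edge ratio above 0.5; the thresholds are
config (`confidence_rules()`), so a stricter or looser reading is one
argument away. The tiers are nested by construction, which the tests assert
on randomized metric vectors, and a locus's cohort-level tier is the best
tier any single sample achieves there (`cohort_tier()`).

## Genomic context

Gene models (BED12 or a GFF3 `gene`/`exon` subset) are reduced to five
region classes: exon, intron, strand-aware 2 kb flanks (`gene_up2k`,
`gene_down2k`) and intergenic. Each call receives the highest-precedence
class it overlaps by >= 1 bp, precedence exon > intron > up2k > down2k >
intergenic — a total rule chosen because each circle is reported with a
single origin class. Per-gene counting (`count_per_gene()`) uses any-overlap
by default, with a containment mode as config, since overlap-versus-
containment is not fixed by the study design. Per-chromosome density is
`circles / (length/1e6)`; its association with `genes/Mb` is a Pearson
correlation with the two-sided p-value from the t transform on n-2 degrees
of freedom, matching how such correlations are reported (r with parametric
p). A generic fixed-width window scan (default 50 kb) backs the genome-wide
density profiles. All internal coordinates are 0-based half-open
(BED-style); GFF3's 1-based closed coordinates are converted at the
boundary, and chromosome names are matched exactly — no silent "chr"
stripping.

## Cohort logic

* **Size classes.** Elements longer than 100 kb are ecDNA, strictly: a
  length of exactly 100,000 bp is still eccDNA. The published group counts
  include small internal inconsistencies; no attempt is made to reconcile
  them, and the package imposes no lower length bound.
* **Length peak.** Lengths are counted in 1 bp bins and smoothed with a
  Gaussian kernel (sd 25 bp, config); the peak is the argmax, with
  near-ties (1e-9 relative) broken toward the smaller length. The 1 bp
  resolution mirrors peaks reported to the base pair (0.358/0.359 kb).
* **Locus identity.** Calls from different samples are the same eccDNA iff
  chromosome, start and end agree within `tolerance_bp`; loci are connected
  components of that relation, represented by their leftmost member. The
  default tolerance is 0 (exact coordinates) because the caller recovers
  exact junctions and no fuzzier notion of identity is defined by the study;
  the tolerance exists for robustness studies.
* **Consistency and overlap.** A locus is interpreted at cohort level when
  present in >= 2 samples of a group; group overlap (Venn) counts are
  computed over the merged loci and satisfy
  `only_a + only_b + both = |A ∪ B|` by construction.

## Differential analysis

Per-gene counts are scaled per sample to the cohort mean total (total-count
scaling; `none` as config), averaged within group, and compared as
`log2(mean_case / mean_control)`. The pseudocount is **substitution for
zero**: a group mean that is exactly 0 is replaced by 0.001 before the
ratio, and nonzero means are never modified. This semantics is forced by the
published table, where zero-group rows print `0.001` verbatim while all
nonzero means are unmodified; it also makes the reported extreme fold
changes (about ±19) exact consequences of the pseudocount. Both means zero
yields a flagged missing value.

The original analysis used edgeR for p-values. Re-implementing edgeR's
negative-binomial machinery is out of scope, so the test here is an exact
Wilcoxon rank-sum — full enumeration of all labelings when both groups have
at most 8 samples (3432 labelings at 7 vs 7), midranks under ties, two-sided
p as twice the smaller tail capped at 1 — with a label-permutation mode as
config. Consequence: the printed PValue/FDR columns are **not** reproduction
targets; the log2FC column and the `p < 0.05`, `|log2FC| > 1` filter (both
strict) are, and on the printed table the filter returns the published
25 genes, 18 up and 7 down. FDR control is Benjamini-Hochberg.

## The synthetic cohort

The generator emulates the study's observable structure without any external
data:

* **Length model.** A mixture: a lognormal body parameterized by its mode
  (358 bp, the reported peak) with shape sigma = 0.75, a uniform tail on
  3–100 kb with weight 0.13, and an ecDNA band uniform on 100.5–998.83 kb
  (the reported ecDNA range) with weight 0.0011. Only a peak, a "<3 kb"
  mass (85.7%) and an ecDNA share are reported, not a parametric form; these
  defaults reproduce all three summaries (planted cohorts give ~85–86%
  below 3 kb and recover the peak within ±15%) and were fixed once.
* **Gene-density coupling.** When on, per-chromosome circle counts are
  allocated proportionally to realized gene counts, emulating the positive
  circles/Mb vs genes/Mb correlation; the correlation-sign recovery is a
  meta-property checked over 40 seeds.
* **Evidence model.** Junction evidence is written directly as soft-clipped
  and outward-discordant SAM records with valid flags and CIGARs — no
  aligner in the loop — which keeps tests hermetic. Each planted circle
  receives `junction_read_depth` junction records (at least one split and
  one discordant when >= 2); background is uniform concordant coverage.
  Circles shorter than the read length get no junction evidence and are
  skipped with a warning. For circles shorter than the insert the two
  discordant positions can invert, so the reverse mate is always placed
  leftmost — the orientation the detection rule defines.
* **Cohort structure.** Two groups of 7 samples; each master locus is
  present in a sample with a group-specific probability (cases lower, as
  case circle yield is reported lower). Per-sample circle-count models are
  not published, so group-level abundance is config, not hard-coded.
* **Not modelled.** Sequencing errors, quality scores, GC/mappability bias,
  and rolling-circle-amplification chimeras. Passing tests therefore show
  correctness of the logic on clean evidence, not robustness to real-library
  noise.

Every generator operation is a pure function of (config, seed): the RNG
state is saved and restored around each call, and per-operation seed offsets
keep the genome, annotation, circles and each sample's reads independent.

## Numerical and design choices

* Tie-breaks are always leftmost (junction refinement, histogram peaks,
  locus representatives) for determinism.
* Desk-scale problem sizes: multi-megabase genomes, 50-circle recovery runs
  with junction depth 6 over background 5, 5,000-circle length-peak
  recovery, 40-seed correlation meta-tests, 10,000-row rule-oracle checks.
  These sizes make the full suite and the acceptance script comfortably
  reproducible on a single CPU while keeping every stochastic check
  well-powered.
* The differential parameter-recovery test plants abundance ratios >= 4 on
  a small-circle background with equal group presence. On desk-scale
  chromosomes the kb-scale tail would blanket whole gene neighborhoods, and
  a handful of planted genes can dominate sample totals, which total-count
  scaling then cancels (the usual composition bias of library-size
  normalization, exaggerated at toy scale); the fixture documents both
  effects.
* `validate_config()` returns every violation, not just the first, and
  `run_pipeline()` refuses to start on an invalid config.

## Known limitations

Single-fragment circles on one chromosome only; no duplicate-read marking;
no re-derivation of the upstream detector's internal circle score; exact
coordinate identity across samples (configurable tolerance, but no
split-read-aware fuzzy matching); the dataset-scale counts of the original
cohort (hundreds of thousands of circles) are not reproducible from
synthetic data and are covered only by structural invariants.
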