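Package: eccatlas
Title: Junction-Evidence Calling and Cohort Characterization of Extrachromosomal Circular DNA
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis workflow for Circle-seq style extrachromosomal circular DNA
    (eccDNA) studies. Implements a desk-scale junction caller (discordant read
    pairs localize the circle interface, soft-clipped split reads fix its exact
    coordinates), a three-tier confidence classification (lconf/conf/hconf),
    genomic characterization (size classes at the 100 kb eccDNA/ecDNA cutoff,
    length-distribution peaks, per-Mb chromosome density against gene density,
    genic-region origin), cross-sample cohort logic (locus identity, consistency
    in at least two samples, group overlap counts), and per-gene differential
    analysis with zero-replacement pseudocount log2 fold change, exact rank-sum
    testing and Benjamini-Hochberg correction. A synthetic-data module generates
    genomes, gene annotations, planted circles and junction-supporting paired-end
    alignments so every stage is testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    GenomicAlignments,
    Rsamtools,
    S4Vectors,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
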