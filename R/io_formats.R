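#' @importFrom utils read.table write.table head combn
#' @import GenomicAlignments
#' @importFrom stats rpois rlnorm rnorm runif rbinom setNames cor.test p.adjust
NULL

## All coordinates inside the package are 0-based half-open (BED-style);
## length = end - start. GFF3 (1-based closed) is converted at the boundary.

CIRCLE_CALL_COLUMNS <- c(
  "chrom", "start", "end", "length", "n_split", "n_discordant",
  "coverage_fraction", "cov_increase_start", "cov_increase_end", "sample_id"
)

GROUP_LABELS <- c("AIONFH", "control")

#' Construct a genome index
#'
#' A genome index binds chromosome names to lengths and fixes the chromosome
#' order used by every per-chromosome statistic.
#'
#' @param chrom character vector of unique chromosome names.
#' @param length positive integer vector of chromosome lengths in bp.
#' @return A `data.frame` with columns `chrom` and `length`.
#' @export
genome_index <- function(chrom, length) {
  chrom <- as.character(chrom)
  length <- as.numeric(length)
  if (length(chrom) == 0L) stop("genome index needs at least one chromosome")
  if (anyDuplicated(chrom)) stop("chromosome names must be unique")
  if (any(!is.finite(length)) || any(length <= 0)) {
    stop("chromosome lengths must be positive")
  }
  data.frame(chrom = chrom, length = length, stringsAsFactors = FALSE)
}

#' Read a genome index from a two-column TSV (chrom, length)
#' @param path path to a tab-separated file with columns `chrom`, `length`.
#' @return A genome index `data.frame`.
#' @export
read_genome_index <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  genome_index(tab$chrom, tab$length)
}

#' Write a genome index
#' @param index genome index `data.frame`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genome_index <- function(index, path) {
  write.table(index, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct (and validate) a circle-call table
#'
#' The canonical container for detected circular-DNA intervals. Each row holds
#' one interval plus its structural-read and coverage evidence: `n_split`
#' junction-confirming soft-clipped reads, `n_discordant` outward-oriented
#' pairs, the fraction of interval bases covered, and the relative
#' coverage-increase ratios at the two boundaries.
#'
#' @param chrom,start,end interval (0-based half-open).
#' @param n_split,n_discordant structural-read support counts.
#' @param coverage_fraction fraction of interval bases with depth >= 1.
#' @param cov_increase_start,cov_increase_end boundary coverage-increase
#'   ratios, each in \[0, 1\].
#' @param sample_id sample identifier.
#' @param genome optional genome index; when given, every `chrom` must be
#'   present and every interval must fit its chromosome.
#' @return A `data.frame` with the canonical circle-call columns.
#' @export
circle_call_table <- function(chrom = character(), start = integer(),
                              end = integer(), n_split = 0L, n_discordant = 0L,
                              coverage_fraction = 0, cov_increase_start = 0,
                              cov_increase_end = 0, sample_id = NA_character_,
                              genome = NULL) {
  n <- max(length(chrom), length(start), length(end))
  if (length(chrom) == 0L || length(start) == 0L || length(end) == 0L) {
    n <- 0L
  }
  start <- rep_len(as.numeric(start), n)
  end <- rep_len(as.numeric(end), n)
  tab <- data.frame(
    chrom = rep_len(as.character(chrom), n),
    start = start,
    end = end,
    length = end - start,
    n_split = rep_len(as.integer(n_split), n),
    n_discordant = rep_len(as.integer(n_discordant), n),
    coverage_fraction = rep_len(as.numeric(coverage_fraction), n),
    cov_increase_start = rep_len(as.numeric(cov_increase_start), n),
    cov_increase_end = rep_len(as.numeric(cov_increase_end), n),
    sample_id = rep_len(as.character(sample_id), n),
    stringsAsFactors = FALSE
  )
  validate_circle_calls(tab, genome)
}

validate_circle_calls <- function(tab, genome = NULL) {
  stopifnot(all(CIRCLE_CALL_COLUMNS %in% names(tab)))
  if (nrow(tab)) {
    if (any(tab$end <= tab$start)) stop("every circle must satisfy end > start")
    if (any(tab$n_split < 0) || any(tab$n_discordant < 0)) {
      stop("support counts must be non-negative")
    }
    ratios <- c(tab$coverage_fraction, tab$cov_increase_start,
                tab$cov_increase_end)
    if (any(ratios < 0 | ratios > 1)) {
      stop("coverage and edge ratios must lie in [0, 1]")
    }
    if (!is.null(genome)) {
      idx <- match(tab$chrom, genome$chrom)
      if (anyNA(idx)) {
        stop("call on chromosome absent from the genome index: ",
             paste(unique(tab$chrom[is.na(idx)]), collapse = ", "))
      }
      if (any(tab$end > genome$length[idx])) {
        stop("call extends beyond its chromosome")
      }
    }
  }
  tab[CIRCLE_CALL_COLUMNS]
}

#' Read a circle-call table
#'
#' Two dialects are supported. `native` is the header-bearing TSV written by
#' [write_circle_table()]. `circlemap` is the headerless 11-column TSV emitted
#' by Circle-Map-style detectors: chrom, start, end, discordant reads, split
#' reads, circle score, mean coverage, stdev, coverage increase at start,
#' coverage increase at end, coverage continuity. Coordinates are 0-based
#' half-open in both dialects; extra trailing columns are ignored with a
#' warning.
#'
#' @param path path to the table.
#' @param dialect `"native"` or `"circlemap"`.
#' @param sample_id sample id attached to every row (circlemap dialect; the
#'   native dialect carries its own column).
#' @return A circle-call `data.frame` (see [circle_call_table()]).
#' @export
read_circle_table <- function(path, dialect = c("native", "circlemap"),
                              sample_id = NA_character_) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  if (dialect == "native") {
    tab <- read.table(path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE, comment.char = "#")
    missing <- setdiff(CIRCLE_CALL_COLUMNS, names(tab))
    if (length(missing)) {
      stop("native circle table is missing columns: ",
           paste(missing, collapse = ", "))
    }
    return(validate_circle_calls(tab))
  }
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (!length(lines)) {
    return(circle_call_table())
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 11L)) {
    stop("malformed circlemap row at line ", which(nf < 11L)[1L],
         ": expected 11 columns, got ", nf[nf < 11L][1L])
  }
  if (any(nf > 11L)) {
    warning("ignoring extra columns beyond 11 in circlemap table")
  }
  mat <- t(vapply(fields, function(f) f[1:11], character(11)))
  num <- suppressWarnings(apply(mat[, 2:11, drop = FALSE], 2, as.numeric))
  num <- matrix(num, nrow = nrow(mat))
  bad <- which(apply(num, 1, anyNA))
  if (length(bad)) {
    stop("malformed circlemap row at line ", bad[1L], ": non-numeric field")
  }
  start <- num[, 1]; end <- num[, 2]
  if (any(end <= start)) {
    stop("malformed circlemap row at line ", which(end <= start)[1L],
         ": end <= start")
  }
  circle_call_table(
    chrom = mat[, 1], start = start, end = end,
    n_discordant = num[, 3], n_split = num[, 4],
    cov_increase_start = pmin(1, pmax(0, num[, 8])),
    cov_increase_end = pmin(1, pmax(0, num[, 9])),
    coverage_fraction = pmin(1, pmax(0, num[, 10])),
    sample_id = sample_id
  )
}

#' Write a circle-call table in the native dialect
#' @param calls circle-call `data.frame`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_circle_table <- function(calls, path) {
  calls <- validate_circle_calls(calls)
  write.table(calls, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a gene-model set
#'
#' @param genes `data.frame` with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand` (0-based half-open gene bodies).
#' @param exons `data.frame` with columns `gene_id`, `start`, `end`; exons are
#'   merged and sorted within each gene and must lie inside the gene body.
#' @return An object of class `gene_models`.
#' @export
gene_models <- function(genes, exons) {
  stopifnot(all(c("gene_id", "chrom", "start", "end", "strand") %in% names(genes)),
            all(c("gene_id", "start", "end") %in% names(exons)))
  if (anyDuplicated(genes$gene_id)) stop("gene ids must be unique")
  if (!all(genes$strand %in% c("+", "-"))) {
    stop("unknown strand symbol: ",
         paste(setdiff(genes$strand, c("+", "-")), collapse = ", "))
  }
  if (any(genes$end <= genes$start)) stop("gene end must exceed start")
  unknown <- setdiff(exons$gene_id, genes$gene_id)
  if (length(unknown)) {
    stop("exon references unknown gene: ", paste(unknown, collapse = ", "))
  }
  merged <- do.call(rbind, lapply(split(exons, exons$gene_id), function(ex) {
    g <- genes[genes$gene_id == ex$gene_id[1L], ]
    if (any(ex$start < g$start) || any(ex$end > g$end)) {
      stop("exon outside gene span for ", ex$gene_id[1L])
    }
    ir <- IRanges::reduce(IRanges::IRanges(ex$start + 1L, ex$end))
    data.frame(gene_id = ex$gene_id[1L],
               start = IRanges::start(ir) - 1L, end = IRanges::end(ir),
               stringsAsFactors = FALSE)
  }))
  if (is.null(merged)) {
    merged <- data.frame(gene_id = character(), start = numeric(),
                         end = numeric(), stringsAsFactors = FALSE)
  }
  rownames(merged) <- NULL
  structure(list(genes = genes[order(genes$chrom, genes$start), ],
                 exons = merged),
            class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat("gene_models: ", nrow(x$genes), " genes, ", nrow(x$exons),
      " merged exons on ", length(unique(x$genes$chrom)), " chromosome(s)\n",
      sep = "")
  invisible(x)
}

#' Read gene models from BED12 or a GFF3 subset
#'
#' The GFF3 subset understood here is `gene` features plus `exon` features
#' linked by `Parent=`; 1-based closed GFF coordinates are converted to the
#' internal 0-based half-open convention. BED12 block definitions provide the
#' exon structure directly.
#'
#' @param path path to the annotation file.
#' @param format `"gff3"` or `"bed12"`.
#' @return A [gene_models()] object.
#' @export
read_gene_models <- function(path, format = c("gff3", "bed12")) {
  format <- match.arg(format)
  if (format == "bed12") {
    tab <- read.table(path, header = FALSE, sep = "\t",
                      stringsAsFactors = FALSE, comment.char = "#")
    if (ncol(tab) < 12L) stop("BED12 requires 12 columns")
    genes <- data.frame(gene_id = tab[[4]], chrom = tab[[1]],
                        start = tab[[2]], end = tab[[3]], strand = tab[[6]],
                        stringsAsFactors = FALSE)
    exons <- do.call(rbind, lapply(seq_len(nrow(tab)), function(i) {
      sizes <- as.integer(strsplit(tab[[11]][i], ",")[[1]])
      starts <- as.integer(strsplit(tab[[12]][i], ",")[[1]])
      data.frame(gene_id = tab[[4]][i],
                 start = tab[[2]][i] + starts,
                 end = tab[[2]][i] + starts + sizes,
                 stringsAsFactors = FALSE)
    }))
    return(gene_models(genes, exons))
  }
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 9L)) stop("malformed GFF3 line")
  mat <- t(vapply(fields, function(f) f[1:9], character(9)))
  attr_field <- function(attrs, key) {
    m <- regmatches(attrs, regexec(paste0("(?:^|;)\\s*", key, "=([^;]+)"), attrs))
    vapply(m, function(r) if (length(r) == 2L) r[2L] else NA_character_,
           character(1))
  }
  type <- mat[, 3]
  is_gene <- type == "gene"
  is_exon <- type == "exon"
  gid <- attr_field(mat[is_gene, 9], "ID")
  if (anyNA(gid)) stop("gene feature without ID attribute")
  genes <- data.frame(gene_id = gid, chrom = mat[is_gene, 1],
                      start = as.numeric(mat[is_gene, 4]) - 1,
                      end = as.numeric(mat[is_gene, 5]),
                      strand = mat[is_gene, 7], stringsAsFactors = FALSE)
  parent <- attr_field(mat[is_exon, 9], "Parent")
  if (anyNA(parent)) stop("exon feature without Parent attribute")
  exons <- data.frame(gene_id = parent,
                      start = as.numeric(mat[is_exon, 4]) - 1,
                      end = as.numeric(mat[is_exon, 5]),
                      stringsAsFactors = FALSE)
  gene_models(genes, exons)
}

#' Write gene models as GFF3
#' @param models a [gene_models()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_models_gff3 <- function(models, path) {
  g <- models$genes
  e <- models$exons
  e$chrom <- g$chrom[match(e$gene_id, g$gene_id)]
  e$strand <- g$strand[match(e$gene_id, g$gene_id)]
  lines <- c(
    "##gff-version 3",
    sprintf("%s\teccatlas\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
            g$chrom, as.integer(g$start) + 1L, as.integer(g$end), g$strand,
            g$gene_id),
    sprintf("%s\teccatlas\texon\t%d\t%d\t.\t%s\t.\tParent=%s",
            e$chrom, as.integer(e$start) + 1L, as.integer(e$end), e$strand,
            e$gene_id)
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a sample manifest
#'
#' A manifest is a TSV with columns `sample_id`, `group`, `path` binding each
#' sample to its cohort arm. Group labels are restricted to `AIONFH` (the
#' osteonecrosis case group) and `control` (femoral-neck-fracture tissue).
#'
#' @param path path to the manifest TSV.
#' @return A `data.frame` with columns `sample_id`, `group`, `path`.
#' @export
read_manifest <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  validate_manifest(tab)
}

validate_manifest <- function(tab) {
  stopifnot(all(c("sample_id", "group") %in% names(tab)))
  if (!"path" %in% names(tab)) tab$path <- NA_character_
  if (anyDuplicated(tab$sample_id)) {
    stop("duplicate sample_id: ",
         paste(unique(tab$sample_id[duplicated(tab$sample_id)]), collapse = ", "))
  }
  bad <- setdiff(unique(tab$group), GROUP_LABELS)
  if (length(bad)) {
    stop("unknown group label(s) ", paste(bad, collapse = ", "),
         "; allowed: ", paste(GROUP_LABELS, collapse = ", "))
  }
  tab[c("sample_id", "group", "path")]
}

#' Write a sample manifest
#' @param manifest manifest `data.frame`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  manifest <- validate_manifest(manifest)
  write.table(manifest, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
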