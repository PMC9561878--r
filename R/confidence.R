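## Three-tier confidence classification for circle calls. Tiers are ordered
## lconf < conf < hconf and nested by construction:
##   lconf : split support >= 1
##   conf  : lconf AND interval coverage >= 80%
##   hconf : conf AND both boundary coverage-increase ratios > 0.5
##           (the edge-ratio reading of the "depth more than twice the
##           surrounding average" criterion)
## A call with no split support is unclassified and excluded from tier
## summaries.

TIER_LEVELS <- c("lconf", "conf", "hconf")

#' Confidence rule thresholds
#'
#' @param min_split minimum split-read support for any tier (default 1).
#' @param min_coverage_fraction coverage threshold for conf and above,
#'   compared inclusively (default 0.80).
#' @param min_edge_ratio boundary coverage-increase threshold for hconf,
#'   compared strictly (default 0.5).
#' @return list of class `confidence_rules`.
#' @export
confidence_rules <- function(min_split = 1L, min_coverage_fraction = 0.80,
                             min_edge_ratio = 0.5) {
  structure(list(min_split = as.integer(min_split),
                 min_coverage_fraction = min_coverage_fraction,
                 min_edge_ratio = min_edge_ratio),
            class = "confidence_rules")
}

#' Classify calls into confidence tiers
#'
#' Total function over calls: returns an ordered factor with levels
#' `lconf < conf < hconf`; calls failing even the lconf predicate (no split
#' support) come back `NA` (unclassified).
#'
#' @param calls circle-call `data.frame`.
#' @param rules a [confidence_rules()] object.
#' @return ordered factor of length `nrow(calls)`.
#' @export
classify_confidence <- function(calls, rules = confidence_rules()) {
  lconf <- calls$n_split >= rules$min_split
  conf <- lconf & calls$coverage_fraction >= rules$min_coverage_fraction
  hconf <- conf & calls$cov_increase_start > rules$min_edge_ratio &
    calls$cov_increase_end > rules$min_edge_ratio
  tier <- ifelse(hconf, "hconf", ifelse(conf, "conf",
                                        ifelse(lconf, "lconf", NA)))
  factor(tier, levels = TIER_LEVELS, ordered = TRUE)
}

#' Attach a `tier` column to a call table
#' @param calls circle-call `data.frame`.
#' @param rules a [confidence_rules()] object.
#' @return `calls` with an added ordered-factor `tier` column.
#' @export
add_confidence_tier <- function(calls, rules = confidence_rules()) {
  calls$tier <- classify_confidence(calls, rules)
  if (anyNA(calls$tier) && nrow(calls)) {
    warning(sum(is.na(calls$tier)),
            " call(s) unclassified (no split support)")
  }
  calls
}

#' Count calls per confidence tier
#'
#' @param calls circle-call `data.frame` (a `tier` column is used if present,
#'   otherwise computed with default rules).
#' @param rules a [confidence_rules()] object.
#' @return named integer vector `c(lconf=, conf=, hconf=)`; counts sum to the
#'   number of classified calls.
#' @export
summarize_tiers <- function(calls, rules = confidence_rules()) {
  tier <- if ("tier" %in% names(calls)) calls$tier else
    classify_confidence(calls, rules)
  out <- table(factor(tier, levels = TIER_LEVELS))
  setNames(as.integer(out), TIER_LEVELS)
}

#' Cohort-level tier of one locus across samples
#'
#' Each tier definition asks that the rule set be met "in at least one
#' sample", so the cohort tier of a locus is the maximum tier achieved by any
#' single sample's call there.
#'
#' @param tiers vector (factor or character) of per-sample tiers at one
#'   locus; `NA` entries are unclassified calls.
#' @return single ordered-factor tier.
#' @export
cohort_tier <- function(tiers) {
  tiers <- factor(as.character(tiers), levels = TIER_LEVELS, ordered = TRUE)
  tiers <- tiers[!is.na(tiers)]
  if (!length(tiers)) stop("no classified call at this locus")
  max(tiers)
}
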