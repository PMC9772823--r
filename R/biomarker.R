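## Digital-PCR biomarker: J2-2P~J2-3 to J2-3 concentration ratio, the 5%
## cutoff call, and the exact Wilcoxon rank-sum group comparison.

#' Relative abundance of J2-2P~J2-3 sequences
#'
#' Ratio of the J2-2P~J2-3 concentration to the J2-3 concentration (both
#' in copies/uL), as a percentage. Reported values are conventionally
#' rounded half-up to one decimal; the unrounded value is returned unless
#' `rounded = TRUE`.
#'
#' @param c_j22p_j23 concentration of J2-2P~J2-3 sequences (copies/uL)
#' @param c_j23 concentration of J2-3-containing sequences (copies/uL),
#'   must be positive
#' @param rounded return the 1-decimal reported value
#' @return percentage ratio (vectorised)
#' @export
computeRatio <- function(c_j22p_j23, c_j23, rounded = FALSE) {
  if (any(is.na(c_j22p_j23)) || any(is.na(c_j23))) {
    stop("concentrations must be non-missing")
  }
  if (any(c_j22p_j23 < 0) || any(c_j23 < 0)) {
    stop("concentrations must be non-negative")
  }
  if (any(c_j23 == 0)) {
    stop("ratio undefined: J2-3 concentration is zero")
  }
  r <- 100 * c_j22p_j23 / c_j23
  if (rounded) roundHalfUp(r, 1L) else r
}

#' Positive/negative call at a ratio cutoff
#'
#' A sample is called positive iff its J2-2P~J2-3 ratio (percent) is at
#' least the cutoff; the boundary value equals the cutoff and is positive.
#'
#' @param ratio_pct percentage ratio(s)
#' @param cutoff percentage cutoff (default 5)
#' @return character vector `"positive"`/`"negative"`
#' @export
callSample <- function(ratio_pct, cutoff = 5) {
  if (any(is.na(ratio_pct))) stop("ratio must be defined")
  ifelse(ratio_pct >= cutoff, "positive", "negative")
}

#' Exact two-sided Wilcoxon rank-sum test
#'
#' For tie-free samples with `nA + nB <= 20`, computes the exact two-sided
#' p-value: over all `choose(nA+nB, nA)` equally likely rank assignments,
#' the probability of a rank sum at least as extreme as observed, two-sided
#' by doubling the smaller one-sided tail (capped at 1). With
#' `twoSided = "minlike"` the two-sided p instead sums the probabilities of
#' all outcomes no more likely than the observed one. Larger or tied
#' samples fall back to the normal approximation with tie correction
#' (attribute `method` then reports `"normal-approximation"`).
#'
#' @param groupA,groupB numeric vectors (non-empty)
#' @param twoSided `"doubling"` (default) or `"minlike"`
#' @return p-value with attribute `method`
#' @export
exactWilcoxon <- function(groupA, groupB, twoSided = c("doubling", "minlike")) {
  twoSided <- match.arg(twoSided)
  if (!length(groupA) || !length(groupB)) stop("both groups must be non-empty")
  nA <- length(groupA); nB <- length(groupB)
  ties <- anyDuplicated(c(groupA, groupB)) > 0L
  if (!ties && nA + nB <= 20L) {
    ## Mann-Whitney U of group A against B
    u <- sum(rank(c(groupA, groupB))[seq_len(nA)]) - nA * (nA + 1) / 2
    if (twoSided == "doubling") {
      lower <- stats::pwilcox(u, nA, nB)
      upper <- 1 - stats::pwilcox(u - 1, nA, nB)
      p <- min(1, 2 * min(lower, upper))
    } else {
      d <- stats::dwilcox(0:(nA * nB), nA, nB)
      p <- sum(d[d <= stats::dwilcox(u, nA, nB) * (1 + 1e-8)])
    }
    attr(p, "method") <- "exact"
  } else {
    p <- stats::wilcox.test(groupA, groupB, exact = FALSE,
                            correct = FALSE)$p.value
    attr(p, "method") <- "normal-approximation"
  }
  p
}

#' Read a digital-PCR sample table
#'
#' Tab-separated input with columns `sample_id`, `group` (`TCL` /
#' `non-TCL`), `c_j22p_j23`, `c_j23` (copies/uL) and optionally
#' `ratio_pct` (instrument-reported ratio; recomputed from concentrations
#' when absent) and `biomed2` (free-text BIOMED-2 result).
#'
#' @param path TSV path
#' @return data.frame of dPCR records with a `ratio_pct` column
#' @export
readDpcrTable <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "group", "c_j22p_j23", "c_j23")
  if (!all(need %in% names(d))) {
    stop("dPCR table must have columns: ", paste(need, collapse = ", "))
  }
  if (!"ratio_pct" %in% names(d)) {
    d$ratio_pct <- computeRatio(d$c_j22p_j23, d$c_j23, rounded = TRUE)
  }
  d
}

#' Path to the bundled digital-PCR example table
#'
#' Per-sample J2-2P~J2-3 and J2-3 concentrations, reported ratios and
#' BIOMED-2 annotations for nine T-cell-lymphoma and six non-TCL bone
#' marrow samples.
#'
#' @return file path
#' @export
dpcrExampleFile <- function() {
  system.file("extdata", "dpcr_tcl_cohort.tsv", package = "TRBrepertoire",
              mustWork = TRUE)
}

#' Cohort summary of the dPCR biomarker
#'
#' Applies the cutoff call to every record, summarises positives/negatives
#' and ratio ranges per group, tests TCL vs non-TCL ratios with
#' [exactWilcoxon()], and counts dPCR-positive samples whose BIOMED-2
#' annotation shows no monoclonal pattern in either TCR gene
#' (BIOMED-2-negative).
#'
#' @param records data.frame as from [readDpcrTable()]
#' @param cutoff ratio cutoff in percent (default 5)
#' @return list with `records` (with `call` column), `group_summary`,
#'   `p_value`, and `n_biomed2_negative_positive`
#' @export
cohortReport <- function(records, cutoff = 5) {
  stopifnot(all(c("sample_id", "group", "ratio_pct") %in% names(records)))
  records$call <- callSample(records$ratio_pct, cutoff)
  gs <- do.call(rbind, lapply(split(records, records$group), function(d) {
    data.frame(group = d$group[1L], n = nrow(d),
               ratio_min = min(d$ratio_pct), ratio_max = max(d$ratio_pct),
               n_positive = sum(d$call == "positive"),
               n_negative = sum(d$call == "negative"),
               stringsAsFactors = FALSE)
  }))
  rownames(gs) <- NULL
  p <- exactWilcoxon(records$ratio_pct[records$group == "TCL"],
                     records$ratio_pct[records$group != "TCL"])
  nneg <- NA_integer_
  if ("biomed2" %in% names(records)) {
    pos <- records$call == "positive"
    known <- !is.na(records$biomed2) & records$biomed2 != "N.A."
    nneg <- sum(pos & known & !grepl("monoclonal", records$biomed2))
  }
  list(records = records, group_summary = gs, p_value = p,
       n_biomed2_negative_positive = nneg)
}
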