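## Category assignment: the eight-way classification of segment chains.

#' Default classification thresholds
#'
#' `intron_min` (15 bp): minimum retained upstream intron certifying a
#' non-recombined (NR), partially recombined (PR) or non-spliced (NS)
#' configuration. `tail_max` (60 bp): maximum unaligned 3' tail for a
#' V-(D)-only read still counted as CR. `c_unaligned_max` (120 bp): maximum
#' unaligned portion for a C-only read counted NS rather than UC.
#' `rss_window` (30 bp): maximum distance from an intergenic segment end to
#' a cryptic 23RSS start for aberrant recombination (AR).
#'
#' @return named list of thresholds
#' @export
defaultThresholds <- function() {
  list(intron_min = 15L, tail_max = 60L, c_unaligned_max = 120L,
       rss_window = 30L)
}

#' Classify one chain from its structural evidence
#'
#' Applies the category rules in precedence order:
#' \enumerate{
#'   \item CH -- cross-strand segments, non-monotonic reference order on
#'     the chain's strand, or two or more C segments;
#'   \item CR -- ordered V-(D)-J-(C); V-(D)-only chains whose read ends
#'     within V or whose unaligned tail is at most `tail_max` are also CR
#'     but excluded from VJ/CDR3 statistics;
#'   \item PR -- D-J-(C) with at least `intron_min` bp of intron
#'     immediately upstream of D; D-only chains with an unaligned tail are
#'     PR but excluded from D-J statistics;
#'   \item AR -- I-J-(C) whose intergenic segment ends within `rss_window`
#'     bp of a cryptic 23RSS start;
#'   \item AS -- a C segment concatenated downstream of a V, D or
#'     intergenic segment, plus I-J-(C) chains failing the AR rule;
#'   \item NR -- J-(C) with at least `intron_min` bp of upstream intron;
#'   \item NS -- C-only with at least `intron_min` bp of upstream intron
#'     and unaligned portions at most `c_unaligned_max`;
#'   \item UC -- everything else (J-(C) without the intron, C-only with a
#'     long unaligned portion, and unmatched configurations).
#' }
#' GT/AG splice motifs are recorded as evidence but never gate a category.
#'
#' @param kinds character vector of chain segment kinds in transcript-sense
#'   order, each one of `"V"`, `"D"`, `"J"`, `"C"`, `"I"`
#' @param nC number of C segments over all aligned segments of the read
#'   (selected and conflicting)
#' @param strandConsistent,orderConsistent chain-consistency evidence over
#'   all aligned segments
#' @param upstreamIntron intron bp immediately upstream of the chain's
#'   first segment
#' @param unalignedHead,unalignedTail unaligned read bp before/after the
#'   chain (transcript sense)
#' @param rssDistance distance (bp) from an initial intergenic segment end
#'   to the nearest downstream cryptic 23RSS start (`NA` when absent)
#' @param thresholds list as from [defaultThresholds()]
#' @return list with `category`, `subtype`, `stats_eligible`
#' @export
categorizeEvidence <- function(kinds, nC, strandConsistent, orderConsistent,
                               upstreamIntron, unalignedHead, unalignedTail,
                               rssDistance, thresholds = defaultThresholds()) {
  th <- thresholds
  ks <- paste(kinds, collapse = "")
  res <- function(category, subtype = NA_character_, eligible = TRUE) {
    list(category = category, subtype = subtype, stats_eligible = eligible)
  }
  ## (1) chimeric
  if (!isTRUE(strandConsistent) || !isTRUE(orderConsistent) || nC >= 2L) {
    return(res("CH", "strand/order/multi-C", FALSE))
  }
  ## (2) completely recombined
  if (grepl("^VD?JC?$", ks)) return(res("CR", "V-(D)-J-(C)"))
  if (grepl("^VD?$", ks) && unalignedTail <= th$tail_max) {
    return(res("CR", "V-(D)-only", eligible = FALSE))
  }
  ## (3) partially recombined
  if (grepl("^DJC?$", ks) && upstreamIntron >= th$intron_min) {
    return(res("PR", "D-J-(C)"))
  }
  if (ks == "D" && unalignedTail > 0L) {
    return(res("PR", "D-only", eligible = FALSE))
  }
  ## (4) aberrant recombination
  if (grepl("^IJC?$", ks) && !is.na(rssDistance) &&
      rssDistance <= th$rss_window) {
    return(res("AR", "I-J-(C)"))
  }
  ## (5) aberrant splicing
  if (grepl("[VDI]C", ks)) {
    first <- regmatches(ks, regexpr("[VDI]C", ks))
    sub <- c(VC = "V-C", DC = "D-C", IC = "I-C")[[first]]
    return(res("AS", sub))
  }
  if (grepl("^IJC?$", ks)) return(res("AS", "I-J-(C)"))
  ## (6) non-recombined
  if (grepl("^JC?$", ks) && upstreamIntron >= th$intron_min) {
    return(res("NR", "J-(C)"))
  }
  ## (7) non-spliced
  if (ks == "C" && upstreamIntron >= th$intron_min &&
      max(unalignedHead, unalignedTail) <= th$c_unaligned_max) {
    return(res("NS", "C-only"))
  }
  ## (8) uncertain
  res("UC", paste0("unresolved:", ks), FALSE)
}

#' Classify a single segment chain
#'
#' Computes chain evidence (sense-order kinds, consistency, upstream
#' intron, unaligned head/tail, cryptic-RSS distance) for one read's
#' segment table and applies [categorizeEvidence()].
#'
#' @param segs one read's segment data.frame as returned by [buildChain()]
#'   (labelled, with a `selected` column)
#' @param locus a [TcrbLocus-class]
#' @param readLen read length in bp (for unaligned head/tail)
#' @param thresholds list as from [defaultThresholds()]
#' @return list with `category`, `subtype`, `stats_eligible` and `evidence`
#' @export
classifyChain <- function(segs, locus, readLen,
                          thresholds = defaultThresholds()) {
  if (is.null(segs) || nrow(segs) == 0L) stop("cannot classify an empty chain")
  rssGr <- rssSites(locus)
  rssStarts <- start(rssGr)[mcols(rssGr)$cryptic %in% TRUE &
                              mcols(rssGr)$spacer == 23L]
  ev <- .chainEvidence(segs, locus, readLen,
                       as.character(locusSequence(locus)), rssStarts)
  out <- categorizeEvidence(ev$kinds, ev$n_C, ev$strand_consistent,
                            ev$order_consistent, ev$upstream_intron_bp,
                            ev$unaligned_head, ev$unaligned_tail,
                            ev$rss_distance, thresholds)
  out$evidence <- ev[setdiff(names(ev), "junctions")]
  out
}

#' Classify all annotated reads
#'
#' Applies [categorizeEvidence()] to every annotated chain of an
#' [annotateReads()] result. Unannotatable reads are excluded.
#'
#' @param annot result of [annotateReads()]
#' @param thresholds list as from [defaultThresholds()]
#' @return data.frame with `read_id`, `sample_id`, `category`, `subtype`,
#'   `stats_eligible` plus the evidence columns of the chain table
#' @export
classifyReads <- function(annot, thresholds = defaultThresholds()) {
  ch <- annot$chains
  ch <- ch[ch$annotated, , drop = FALSE]
  if (nrow(ch) == 0L) {
    return(cbind(ch, category = character(0), subtype = character(0),
                 stats_eligible = logical(0)))
  }
  res <- lapply(seq_len(nrow(ch)), function(i) {
    categorizeEvidence(strsplit(ch$kinds[i], "")[[1L]], ch$n_C[i],
                       ch$strand_consistent[i], ch$order_consistent[i],
                       ch$upstream_intron_bp[i], ch$unaligned_head[i],
                       ch$unaligned_tail[i], ch$rss_distance[i], thresholds)
  })
  ch$category <- vapply(res, `[[`, character(1), "category")
  ch$subtype <- vapply(res, `[[`, character(1), "subtype")
  ch$stats_eligible <- vapply(res, `[[`, logical(1), "stats_eligible")
  ch
}

#' Splice-motif support summary for aberrantly spliced reads
#'
#' For each AS configuration (I-C, V-C, D-C, I-J-(C)) reports the fraction
#' of aberrant junctions with a GT donor immediately after the upstream
#' segment and an AG acceptor immediately before the downstream segment in
#' the reference, together with the modal donor position (and its offset
#' from the D1 segment start, the recurrent intergenic donor).
#'
#' @param annot result of [annotateReads()]
#' @param labels result of [classifyReads()]
#' @param locus a [TcrbLocus-class]
#' @return data.frame keyed by subtype with columns `n`, `donor_gt_frac`,
#'   `acceptor_ag_frac`, `modal_donor_pos`, `modal_donor_offset_d1`; zero
#'   rows when no AS reads exist
#' @export
spliceEvidenceSummary <- function(annot, labels, locus) {
  empty <- data.frame(subtype = character(), n = integer(),
                      donor_gt_frac = numeric(), acceptor_ag_frac = numeric(),
                      modal_donor_pos = integer(),
                      modal_donor_offset_d1 = integer(),
                      stringsAsFactors = FALSE)
  as <- labels[labels$category == "AS", , drop = FALSE]
  if (nrow(as) == 0L || is.null(annot$junctions)) return(empty)
  tab <- .segTable(locus)
  d1start <- tab$start[tab$name == "D1"]
  jn <- annot$junctions[annot$junctions$read_id %in% as$read_id, , drop = FALSE]
  ## the aberrant junction: upstream V/D/I joined to C, or I joined to J
  ab <- jn[(jn$up_kind %in% c("V", "D", "I") & jn$down_kind == "C") |
             (jn$up_kind == "I" & jn$down_kind == "J"), , drop = FALSE]
  if (nrow(ab) == 0L) return(empty)
  key <- paste0(ab$up_kind, "-", ab$down_kind)
  out <- lapply(split(seq_len(nrow(ab)), key), function(ii) {
    don <- ab$up_ref_end[ii]
    mode <- as.integer(names(sort(table(don), decreasing = TRUE))[1L])
    data.frame(subtype = key[ii[1L]], n = length(ii),
               donor_gt_frac = mean(ab$donor_GT[ii], na.rm = TRUE),
               acceptor_ag_frac = mean(ab$acceptor_AG[ii], na.rm = TRUE),
               modal_donor_pos = mode,
               modal_donor_offset_d1 = mode - d1start,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
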