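## Read annotation: alignment, post-processing, labelling and per-read
## chain evidence -- the contract consumed by the classifier.

## label each aligned segment with the gene segment its reference interval
## overlaps; alignments extending into the upstream intron keep the gene
## label plus an upstream_intron_bp count; alignments overlapping no
## (functional-kind) segment are intergenic ("I")
.labelSegments <- function(segs, locus, segTable = NULL) {
  tab <- if (is.null(segTable)) .segTable(locus) else segTable
  n <- nrow(segs)
  segs$name <- rep("I", n)
  segs$kind <- rep("I", n)
  segs$upstream_intron_bp <- rep(0L, n)
  for (i in seq_len(n)) {
    ov <- pmin(segs$ref_end[i], tab$end) - pmax(segs$ref_start[i], tab$start) + 1L
    hit <- which(ov > 0L & tab$kind != "pseudo-J")
    if (!length(hit)) next
    ## largest overlap wins; ties go to the most downstream segment
    best <- hit[order(-ov[hit], -tab$start[hit])][1L]
    segs$name[i] <- tab$name[best]
    segs$kind[i] <- tab$kind[best]
    segs$upstream_intron_bp[i] <- max(0L, tab$start[best] - segs$ref_start[i])
  }
  segs
}

## per-read chain evidence in transcript-sense order ("+" chains read
## left-to-right; "-" chains reversed)
.chainEvidence <- function(segs, locus, readLen, locusSeq, rssStarts) {
  sel <- segs[segs$selected, , drop = FALSE]
  strand <- attr(segs, "chain_strand")
  if (is.null(strand)) strand <- sel$strand[1L]
  ord <- order(sel$read_start)
  if (strand == "-") ord <- rev(ord)
  sel <- sel[ord, , drop = FALSE]
  kinds <- ifelse(sel$kind == "pseudo-J", "I", sel$kind)

  ## head/tail in transcript sense
  headBp <- min(segs$read_start[segs$selected]) - 1L
  tailBp <- readLen - max(segs$read_end[segs$selected])
  if (strand == "-") { tmp <- headBp; headBp <- tailBp; tailBp <- tmp }

  allSorted <- segs[order(segs$read_start), , drop = FALSE]
  strandConsistent <- length(unique(allSorted$strand)) == 1L
  orderConsistent <- strandConsistent && (
    nrow(allSorted) <= 1L ||
      if (strand == "+") all(diff(allSorted$ref_start) > 0)
      else all(diff(allSorted$ref_start) < 0))
  nC <- sum(allSorted$kind == "C")

  rss <- NA_integer_
  if (kinds[1L] == "I" && strand == "+" && length(rssStarts)) {
    d <- rssStarts - sel$ref_end[1L]
    d <- d[d >= 0L]
    if (length(d)) rss <- min(d)
  }

  ## junction evidence between consecutive sense segments
  junc <- NULL
  if (nrow(sel) > 1L) {
    up <- sel[-nrow(sel), , drop = FALSE]
    dn <- sel[-1L, , drop = FALSE]
    donorGT <- substring(locusSeq, up$ref_end + 1L, up$ref_end + 2L) == "GT"
    acceptAG <- substring(locusSeq, dn$ref_start - 2L, dn$ref_start - 1L) == "AG"
    if (strand == "-") { donorGT <- rep(NA, nrow(up)); acceptAG <- donorGT }
    junc <- data.frame(up_name = up$name, up_kind = ifelse(up$kind == "pseudo-J", "I", up$kind),
                       down_name = dn$name, down_kind = ifelse(dn$kind == "pseudo-J", "I", dn$kind),
                       up_ref_end = up$ref_end, down_ref_start = dn$ref_start,
                       donor_GT = donorGT, acceptor_AG = acceptAG,
                       stringsAsFactors = FALSE)
  }

  firstOf <- function(kk) {
    i <- which(kinds == kk)
    if (length(i)) sel$name[i[1L]] else NA_character_
  }
  jIdx <- which(kinds == "J")[1L]
  vIdx <- which(kinds == "V")[1L]
  list(kinds = kinds, strand = strand,
       unaligned_head = headBp, unaligned_tail = tailBp,
       strand_consistent = strandConsistent,
       order_consistent = orderConsistent,
       n_C = nC, upstream_intron_bp = sel$upstream_intron_bp[1L],
       rss_distance = rss,
       v_name = firstOf("V"), d_name = firstOf("D"),
       j_name = firstOf("J"), c_name = firstOf("C"),
       v_read_end = if (!is.na(vIdx)) sel$read_end[vIdx] else NA_integer_,
       j_read_start = if (!is.na(jIdx)) sel$read_start[jIdx] else NA_integer_,
       j_ref_start = if (!is.na(jIdx)) sel$ref_start[jIdx] else NA_integer_,
       j_ref_end = if (!is.na(jIdx)) sel$ref_end[jIdx] else NA_integer_,
       junctions = junc)
}

#' Annotate processed reads against the locus
#'
#' Runs the per-read annotation pipeline: local alignment ([alignRead()]),
#' removal of redundant homology duplicates, merging of broken alignments
#' ([mergeBroken()]), splitting of read overlaps at splice motifs
#' ([splitOverlapAtSplice()]), gene-segment labelling, out-of-order C1
#' reannotation ([fixCOrder()]) and chain selection ([buildChain()]).
#' Reads with no alignment are reported unannotatable and excluded from
#' classification.
#'
#' @param processed data.frame from [preprocessReads()] (`read_id`,
#'   `sample_id`, `sequence`), or a named character vector of sequences
#' @param locus a [TcrbLocus-class]
#' @param minSegLen minimum aligned segment length (default 20)
#' @param minIdentity minimum alignment identity (default 0.85)
#' @param closeThreshold broken-alignment gap threshold (default 30)
#' @return list with `segments` (all aligned segments, labelled, with
#'   `selected` marking chain membership), `chains` (one row per read with
#'   sense-order kinds and evidence columns) and `junctions` (per adjacent
#'   chain pair: GT/AG splice support)
#' @export
annotateReads <- function(processed, locus, minSegLen = 20L,
                          minIdentity = 0.85, closeThreshold = 30L) {
  if (!is.data.frame(processed)) {
    processed <- data.frame(read_id = names(processed),
                            sample_id = NA_character_,
                            sequence = unname(processed),
                            stringsAsFactors = FALSE)
  }
  idx <- locusIndex(locus)
  locusSeq <- idx$seq
  segTab <- .segTable(locus)
  rssGr <- rssSites(locus)
  rssStarts <- start(rssGr)[mcols(rssGr)$cryptic %in% TRUE &
                              mcols(rssGr)$spacer == 23L]

  segList <- vector("list", nrow(processed))
  juncList <- vector("list", nrow(processed))
  chainRows <- vector("list", nrow(processed))

  for (i in seq_len(nrow(processed))) {
    rid <- processed$read_id[i]
    sq <- processed$sequence[i]
    segs <- alignRead(sq, locus, index = idx, minSegLen = minSegLen,
                      minIdentity = minIdentity)
    if (nrow(segs) == 0L) {
      chainRows[[i]] <- list(read_id = rid,
                             sample_id = processed$sample_id[i],
                             annotated = FALSE)
      next
    }
    ## canonical orientation: reverse-complement the read when the minus
    ## strand dominates, so one orientation is post-processed and
    ## classified; the original orientation is kept as metadata
    flipped <- sum(segs$matches[segs$strand == "-"]) >
      sum(segs$matches[segs$strand == "+"])
    if (flipped) {
      L <- nchar(sq)
      sq <- .revcomp(sq)
      tmp <- segs$read_start
      segs$read_start <- L - segs$read_end + 1L
      segs$read_end <- L - tmp + 1L
      segs$strand <- ifelse(segs$strand == "+", "-", "+")
      segs <- segs[order(segs$read_start, segs$read_end), , drop = FALSE]
    }
    segs <- .dedupeContained(segs)
    segs <- mergeBroken(segs, closeThreshold = closeThreshold)
    segs <- splitOverlapAtSplice(segs, locus, readSeq = sq)
    segs <- .labelSegments(segs, locus, segTable = segTab)
    segs <- fixCOrder(segs, locus, segTable = segTab)
    segs <- buildChain(segs)
    ev <- .chainEvidence(segs, locus, nchar(sq), locusSeq, rssStarts)

    segs <- cbind(read_id = rid, segs, stringsAsFactors = FALSE)
    segList[[i]] <- segs
    if (!is.null(ev$junctions)) {
      juncList[[i]] <- cbind(read_id = rid, ev$junctions,
                             stringsAsFactors = FALSE)
    }
    chainRows[[i]] <- list(
      read_id = rid, sample_id = processed$sample_id[i], annotated = TRUE,
      chain_strand = if (flipped) "-" else ev$strand,
      kinds = paste(ev$kinds, collapse = ""),
      n_segments = length(ev$kinds),
      unaligned_head = ev$unaligned_head, unaligned_tail = ev$unaligned_tail,
      strand_consistent = ev$strand_consistent,
      order_consistent = ev$order_consistent, n_C = ev$n_C,
      upstream_intron_bp = ev$upstream_intron_bp,
      rss_distance = ev$rss_distance,
      v_name = ev$v_name, d_name = ev$d_name, j_name = ev$j_name,
      c_name = ev$c_name, v_read_end = ev$v_read_end,
      j_read_start = ev$j_read_start, j_ref_start = ev$j_ref_start,
      j_ref_end = ev$j_ref_end, read_length = nchar(sq))
  }

  fill <- list(chain_strand = NA_character_, kinds = NA_character_,
               n_segments = NA_integer_, unaligned_head = NA_integer_,
               unaligned_tail = NA_integer_, strand_consistent = NA,
               order_consistent = NA, n_C = NA_integer_,
               upstream_intron_bp = NA_integer_, rss_distance = NA_integer_,
               v_name = NA_character_, d_name = NA_character_,
               j_name = NA_character_, c_name = NA_character_,
               v_read_end = NA_integer_, j_read_start = NA_integer_,
               j_ref_start = NA_integer_, j_ref_end = NA_integer_,
               read_length = NA_integer_)
  chains <- do.call(rbind, lapply(chainRows, function(r) {
    miss <- setdiff(names(fill), names(r))
    as.data.frame(c(r, fill[miss]), stringsAsFactors = FALSE)
  }))
  list(segments = do.call(rbind, segList),
       junctions = do.call(rbind, juncList),
       chains = chains)
}
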