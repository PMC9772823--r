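## Post-processing of aligned segments: merging broken alignments,
## C1->C2 reannotation, splitting read overlaps at splice motifs, and
## selection of the best strand/order-consistent chain.

#' Merge broken alignments
#'
#' Two read-adjacent, same-strand aligned segments that are close in both
#' the read and the reference (both gaps between 0 and `closeThreshold`)
#' are merged when the two gap sizes differ by less than half of the larger
#' gap; abutting segments (both gaps zero) are always merged. Applied
#' iteratively to a fixpoint. Such breaks arise from low-quality bases in
#' the middle of one true alignment; gap bases are counted as mismatches in
#' the merged identity.
#'
#' @param segs data.frame of aligned segments (as from [alignRead()]),
#'   sorted by read position
#' @param closeThreshold maximum gap (bp) for a pair to be considered
#'   broken (default 30; smaller than any locus intron so real junctions
#'   are never merged)
#' @return data.frame with merged segments
#' @export
mergeBroken <- function(segs, closeThreshold = 30L) {
  repeat {
    n <- nrow(segs)
    if (n <= 1L) break
    o <- order(segs$read_start, segs$read_end)
    if (any(o != seq_len(n))) segs <- segs[o, , drop = FALSE]
    rs <- segs$read_start; re <- segs$read_end
    fs <- segs$ref_start; fe <- segs$ref_end
    str <- segs$strand
    same <- str[-n] == str[-1L]
    dr <- rs[-1L] - re[-n] - 1L
    dg <- ifelse(str[-n] == "+", fs[-1L] - fe[-n] - 1L, fs[-n] - fe[-1L] - 1L)
    ok <- same & dr >= 0L & dg >= 0L & dr <= closeThreshold &
      dg <= closeThreshold &
      ((dr == 0L & dg == 0L) | abs(dr - dg) < pmax(dr, dg) / 2)
    i <- which(ok)[1L]
    if (is.na(i)) break
    segs$read_end[i] <- re[i + 1L]
    segs$ref_start[i] <- min(fs[i], fs[i + 1L])
    segs$ref_end[i] <- max(fe[i], fe[i + 1L])
    segs$matches[i] <- segs$matches[i] + segs$matches[i + 1L]
    segs$identity[i] <- segs$matches[i] /
      (segs$read_end[i] - segs$read_start[i] + 1L)
    segs <- segs[-(i + 1L), , drop = FALSE]
  }
  rownames(segs) <- NULL
  segs
}

#' Reannotate out-of-order C1 segments as C2
#'
#' The two constant segments are near-identical, so a sequencing error can
#' flip the best alignment from C2 to C1. When a C1-labelled segment breaks
#' the reference-order consistency of its read while the homologous C2
#' placement would restore it, the segment is relabelled C2 and its
#' reference interval remapped. The symmetric C2 to C1 relabelling is not
#' performed.
#'
#' @param segs labelled segment data.frame (columns `name`, `kind` present)
#' @param locus a [TcrbLocus-class]
#' @param segTable optional precomputed segment table (internal speed-up)
#' @return data.frame with relabelled segments (same row count)
#' @export
fixCOrder <- function(segs, locus, segTable = NULL) {
  n <- nrow(segs)
  if (n <= 1L) return(segs)
  tab <- if (is.null(segTable)) .segTable(locus) else segTable
  cs <- tab[tab$kind == "C", ]
  if (nrow(cs) != 2L) return(segs)
  c1 <- cs[1L, ]; c2 <- cs[2L, ]
  if (!any(segs$name == c1$name)) return(segs)
  shift <- c2$start - c1$start
  segs <- segs[order(segs$read_start, segs$read_end), , drop = FALSE]
  orderedAt <- function(st, i) {
    ok <- TRUE
    if (i > 1L) ok <- ok && st[i] > st[i - 1L]
    if (i < n) ok <- ok && st[i + 1L] > st[i]
    ok
  }
  for (i in seq_len(n)) {
    if (segs$name[i] != c1$name || segs$strand[i] != "+") next
    st <- segs$ref_start
    if (orderedAt(st, i)) next
    st2 <- st; st2[i] <- st[i] + shift
    if (orderedAt(st2, i)) {
      segs$name[i] <- c2$name
      segs$ref_start[i] <- segs$ref_start[i] + shift
      segs$ref_end[i] <- segs$ref_end[i] + shift
      if ("upstream_intron_bp" %in% names(segs)) {
        segs$upstream_intron_bp[i] <- max(0L, c2$start - segs$ref_start[i])
      }
    }
  }
  rownames(segs) <- NULL
  segs
}

#' Split read-overlapping neighbour alignments at a splice motif
#'
#' When two read-adjacent segments overlap on the read, a single breakpoint
#' is placed inside the overlap such that the upstream segment ends
#' immediately before a GT donor and the downstream segment starts
#' immediately after an AG acceptor in the reference. Among several
#' GT/AG-consistent breakpoints the one maximising the number of matching
#' bases is chosen (requires `readSeq`; otherwise the leftmost candidate).
#' With no consistent candidate the overlap is split at its midpoint and
#' the pair flagged `no_splice_support`.
#'
#' @param segs segment data.frame sorted by read position
#' @param locus a [TcrbLocus-class]
#' @param readSeq optional read sequence for identity re-scoring
#' @return data.frame with non-overlapping segments and a `flags` column
#' @export
splitOverlapAtSplice <- function(segs, locus, readSeq = NULL) {
  n <- nrow(segs)
  if (!"flags" %in% names(segs)) segs$flags <- rep("", max(n, 0L))
  if (n <= 1L) return(segs)
  o <- order(segs$read_start, segs$read_end)
  if (any(o != seq_len(n))) segs <- segs[o, , drop = FALSE]
  if (all(segs$read_end[-n] < segs$read_start[-1L])) return(segs)
  s <- as.character(locusSequence(locus))
  rchars <- if (!is.null(readSeq)) strsplit(readSeq, "")[[1L]] else NULL
  fchars <- strsplit(s, "")[[1L]]

  for (i in seq_len(n - 1L)) {
    a <- segs[i, ]; b <- segs[i + 1L, ]
    ov <- a$read_end - b$read_start + 1L
    if (ov <= 0L) next
    if (a$strand != "+" || b$strand != "+") next
    ## candidate breakpoints: read position where the upstream segment ends
    cand <- (b$read_start - 1L):a$read_end
    aEnd <- a$ref_end - (a$read_end - cand)       # upstream new ref end
    bStart <- b$ref_start + (cand + 1L - b$read_start)  # downstream new ref start
    okGT <- substring(s, aEnd + 1L, aEnd + 2L) == "GT"
    okAG <- substring(s, bStart - 2L, bStart - 1L) == "AG"
    good <- cand[okGT & okAG & cand >= a$read_start & cand + 1L <= b$read_end]
    if (length(good)) {
      if (!is.null(rchars) && length(good) > 1L) {
        score <- vapply(good, function(bp) {
          mA <- sum(rchars[a$read_start:bp] ==
                      fchars[a$ref_start:(a$ref_end - (a$read_end - bp))])
          mB <- sum(rchars[(bp + 1L):b$read_end] ==
                      fchars[(b$ref_start + (bp + 1L - b$read_start)):b$ref_end])
          mA + mB
        }, numeric(1))
        bp <- good[which.max(score)]
      } else bp <- good[1L]
      flag <- ""
    } else {
      bp <- b$read_start - 1L + ov %/% 2L
      bp <- min(max(bp, a$read_start), b$read_end - 1L)
      flag <- "no_splice_support"
    }
    segs$ref_end[i] <- a$ref_end - (a$read_end - bp)
    segs$read_end[i] <- bp
    segs$ref_start[i + 1L] <- b$ref_start + (bp + 1L - b$read_start)
    segs$read_start[i + 1L] <- bp + 1L
    if (nzchar(flag)) {
      segs$flags[i] <- paste0(segs$flags[i], flag)
      segs$flags[i + 1L] <- paste0(segs$flags[i + 1L], flag)
    }
    for (j in c(i, i + 1L)) {
      len <- segs$read_end[j] - segs$read_start[j] + 1L
      if (!is.null(rchars)) {
        segs$matches[j] <- sum(rchars[segs$read_start[j]:segs$read_end[j]] ==
                                 fchars[segs$ref_start[j]:segs$ref_end[j]])
      } else {
        segs$matches[j] <- min(segs$matches[j], len)
      }
      segs$identity[j] <- segs$matches[j] / len
    }
  }
  rownames(segs) <- NULL
  segs
}

#' Select the highest-scoring consistent chain of segments
#'
#' Picks the subset of segments maximising total aligned read length
#' subject to strand consistency and strict reference-order consistency
#' (increasing reference position along the read on `+`, decreasing on
#' `-`), with non-overlapping read intervals. Ties are broken towards more
#' segments, then the leftmost read start, then the `+` strand. Segments
#' excluded by chaining are retained (`selected = FALSE`) as conflicting
#' evidence for chimera detection.
#'
#' @param segs segment data.frame (>= 1 row)
#' @return `segs` sorted by read position with a logical `selected` column;
#'   attributes `chain_strand` and `chain_score` carry the chain summary
#' @export
buildChain <- function(segs) {
  if (is.null(segs) || nrow(segs) == 0L) stop("cannot chain an empty segment set")
  segs <- segs[order(segs$read_start, segs$read_end), , drop = FALSE]
  n <- nrow(segs)
  ## lexicographic preference: higher score, then more segments, then
  ## leftmost chain start, then "+" strand
  betterThan <- function(x, y) {
    if (is.null(y)) return(TRUE)
    if (x$score != y$score) return(x$score > y$score)
    if (x$nseg != y$nseg) return(x$nseg > y$nseg)
    if (x$start != y$start) return(x$start < y$start)
    x$strand == "+" && y$strand != "+"
  }
  best <- NULL
  for (str in c("+", "-")) {
    ii <- which(segs$strand == str)
    if (!length(ii)) next
    m <- length(ii)
    len <- segs$read_end[ii] - segs$read_start[ii] + 1L
    ## DP over read-sorted segments of one strand
    score <- len; nseg <- rep(1L, m); prev <- rep(0L, m)
    st <- segs$read_start[ii]
    for (b in seq_len(m)) {
      for (a in seq_len(b - 1L)) {
        A <- ii[a]; B <- ii[b]
        compat <- segs$read_start[B] > segs$read_end[A] &&
          (if (str == "+") segs$ref_start[B] > segs$ref_start[A]
           else segs$ref_start[B] < segs$ref_start[A])
        if (!compat) next
        cand <- score[a] + len[b]
        take <- cand > score[b] ||
          (cand == score[b] && nseg[a] + 1L > nseg[b]) ||
          (cand == score[b] && nseg[a] + 1L == nseg[b] && st[a] < st[b])
        if (take) {
          score[b] <- cand; nseg[b] <- nseg[a] + 1L; prev[b] <- a
          st[b] <- st[a]
        }
      }
    }
    for (e in seq_len(m)) {
      cand <- list(score = score[e], nseg = nseg[e], start = st[e],
                   strand = str, end = e, ii = ii, prev = prev)
      if (betterThan(cand, best)) best <- cand
    }
  }
  sel <- integer(0); cur <- best$end
  while (cur != 0L) { sel <- c(cur, sel); cur <- best$prev[cur] }
  best$idx <- best$ii[sel]
  segs$selected <- seq_len(n) %in% best$idx
  rownames(segs) <- NULL
  attr(segs, "chain_strand") <- best$strand
  attr(segs, "chain_score") <- best$score
  segs
}
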