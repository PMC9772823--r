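## Local alignment of processed reads against the locus: exact k-mer
## seeding, diagonal clustering, X-drop extension; indel-containing
## candidates are refined with Biostrings::pairwiseAlignment.

#' Build a k-mer index of the locus
#'
#' Hash from every k-mer of the locus sequence to its start positions,
#' reused across reads by [alignRead()] / [annotateReads()].
#'
#' @param locus a [TcrbLocus-class]
#' @param k k-mer size (default 12)
#' @return an opaque index list
#' @export
locusIndex <- function(locus, k = 12L) {
  s <- as.character(locusSequence(locus))
  n <- nchar(s) - k + 1L
  kmers <- substring(s, seq_len(n), seq_len(n) + k - 1L)
  env <- list2env(split(seq_len(n), kmers), hash = TRUE)
  list(k = k, env = env, seq = s, chars = strsplit(s, "")[[1L]],
       len = nchar(s))
}

## X-drop extension: number of bases the alignment can be extended from
## (ri, fi) exclusive, in direction `step` (+1/-1); match +1, mismatch -3,
## stop when the score drops 12 below its running maximum
.xdropExtend <- function(rchars, fchars, ri, fi, step) {
  best <- 0L; bestLen <- 0L; score <- 0L; len <- 0L
  nr <- length(rchars); nf <- length(fchars)
  repeat {
    i <- ri + step * (len + 1L)
    j <- fi + step * (len + 1L)
    if (i < 1L || i > nr || j < 1L || j > nf) break
    len <- len + 1L
    score <- score + (if (rchars[i] == fchars[j]) 1L else -3L)
    if (score > best) { best <- score; bestLen <- len }
    if (best - score > 12L) break
  }
  bestLen
}

## core single-orientation alignment; returns data.frame of candidate
## segments in the coordinates of `seqStr`
.alignOrient <- function(seqStr, idx, minSegLen, minIdentity) {
  empty <- data.frame(read_start = integer(), read_end = integer(),
                      ref_start = integer(), ref_end = integer(),
                      matches = integer(), identity = numeric())
  L <- nchar(seqStr)
  k <- idx$k
  if (L < k) return(empty)
  kms <- substring(seqStr, seq_len(L - k + 1L), seq_len(L - k + 1L) + k - 1L)
  hits <- mget(kms, envir = idx$env, ifnotfound = list(NULL))
  lens <- lengths(hits)
  if (!sum(lens)) return(empty)
  rp <- rep.int(seq_along(kms), lens)
  fp <- unlist(hits, use.names = FALSE)
  dg <- fp - rp
  o <- order(dg, rp)
  rp <- rp[o]; fp <- fp[o]; dg <- dg[o]
  brk <- c(TRUE, diff(dg) > 8L | abs(diff(rp)) > 40L)
  cid <- cumsum(brk)

  rchars <- strsplit(seqStr, "")[[1L]]
  fchars <- idx$chars
  clusters <- split(seq_along(rp), cid)
  nc <- length(clusters)
  RS <- integer(nc); RE <- integer(nc); FS <- integer(nc); FE <- integer(nc)
  MM <- integer(nc)
  for (ci in seq_len(nc)) {
    ii <- clusters[[ci]]
    rs <- min(rp[ii]); re <- max(rp[ii]) + k - 1L
    fs <- min(fp[ii]); fe <- max(fp[ii]) + k - 1L
    if (dg[ii[1L]] == dg[ii[length(ii)]]) {
      eL <- .xdropExtend(rchars, fchars, rs, fs, -1L)
      eR <- .xdropExtend(rchars, fchars, re, fe, +1L)
      rs <- rs - eL; fs <- fs - eL; re <- re + eR; fe <- fe + eR
      m <- sum(rchars[rs:re] == fchars[fs:fe])
    } else {
      ## indel-containing candidate: banded refinement on the substrings
      r0 <- max(1L, rs - 12L); r1 <- min(L, re + 12L)
      f0 <- max(1L, fs - 12L); f1 <- min(idx$len, fe + 12L)
      pa <- Biostrings::pairwiseAlignment(
        substring(seqStr, r0, r1), substring(idx$seq, f0, f1),
        type = "local")
      pr <- Biostrings::pattern(pa)
      su <- Biostrings::subject(pa)
      alen <- max(end(pr) - start(pr), end(su) - start(su)) + 1L
      m <- round(Biostrings::nmatch(pa) / alen * (end(pr) - start(pr) + 1L))
      rs <- r0 + start(pr) - 1L; re <- r0 + end(pr) - 1L
      fs <- f0 + start(su) - 1L; fe <- f0 + end(su) - 1L
    }
    RS[ci] <- rs; RE[ci] <- re; FS[ci] <- fs; FE[ci] <- fe; MM[ci] <- m
  }
  out <- data.frame(read_start = RS, read_end = RE, ref_start = FS,
                    ref_end = FE, matches = MM,
                    identity = MM / (RE - RS + 1L))
  out[(out$read_end - out$read_start + 1L) >= minSegLen &
        out$identity >= minIdentity, , drop = FALSE]
}

#' Align one processed read against the locus
#'
#' Reports all local alignments of the read (both strands) with identity at
#' least `minIdentity` and length at least `minSegLen`. Minus-strand hits
#' are reported in the original read coordinates with `strand = "-"`.
#'
#' @param seq read sequence (character)
#' @param locus a [TcrbLocus-class]
#' @param index optional precomputed [locusIndex()]
#' @param minSegLen minimum aligned length (default 20)
#' @param minIdentity minimum identity fraction (default 0.85)
#' @return data.frame of aligned segments: `read_start`, `read_end`,
#'   `ref_start`, `ref_end`, `strand`, `matches`, `identity`; zero rows when
#'   the read is unannotatable
#' @export
alignRead <- function(seq, locus, index = NULL, minSegLen = 20L,
                      minIdentity = 0.85) {
  if (is.null(index)) index <- locusIndex(locus)
  L <- nchar(seq)
  plus <- .alignOrient(seq, index, minSegLen, minIdentity)
  plus$strand <- rep("+", nrow(plus))
  rcseq <- .revcomp(seq)
  minus <- .alignOrient(rcseq, index, minSegLen, minIdentity)
  if (nrow(minus)) {
    tmp <- minus$read_start
    minus$read_start <- L - minus$read_end + 1L
    minus$read_end <- L - tmp + 1L
    minus$strand <- "-"
  } else {
    minus$strand <- character(0)
  }
  out <- rbind(plus, minus)
  out <- out[order(out$read_start, out$read_end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## drop redundant alignments: when two segments overlap on >= 80% of the
## shorter read interval, keep the one with more matching bases (then
## higher identity, then leftmost reference). This removes C1/C2-style
## homology duplicates while preserving genuinely distinct placements.
.dedupeContained <- function(segs) {
  n <- nrow(segs)
  if (n <= 1L) return(segs)
  o <- order(-segs$matches, -segs$identity, segs$ref_start)
  keep <- logical(n)
  for (i in o) {
    ov <- FALSE
    for (j in which(keep)) {
      inter <- min(segs$read_end[i], segs$read_end[j]) -
        max(segs$read_start[i], segs$read_start[j]) + 1L
      shorter <- min(segs$read_end[i] - segs$read_start[i],
                     segs$read_end[j] - segs$read_start[j]) + 1L
      if (inter >= 0.8 * shorter) { ov <- TRUE; break }
    }
    if (!ov) keep[i] <- TRUE
  }
  out <- segs[keep, , drop = FALSE]
  out <- out[order(out$read_start, out$read_end), , drop = FALSE]
  rownames(out) <- NULL
  out
}
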