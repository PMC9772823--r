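## independent oracles used to cross-check the implementation

## --- category oracle -------------------------------------------------------
## Re-derives the eight-way category from first principles: each category's
## defining predicate is tested independently on explicit kind templates,
## then the stated precedence (CH, CR, PR, AR, AS, NR, NS, UC) is applied.
## Structurally independent from categorizeEvidence (template matching by
## identical(), no regular expressions).
oracleCategory <- function(kinds, nC, strandConsistent, orderConsistent,
                           intron, head, tail, rss,
                           th = defaultThresholds()) {
  anyTemplate <- function(templates) {
    any(vapply(templates, function(t) identical(kinds, t), logical(1)))
  }
  isCH <- !strandConsistent || !orderConsistent || nC >= 2L
  isCRfull <- anyTemplate(list(c("V", "J"), c("V", "D", "J"),
                               c("V", "J", "C"), c("V", "D", "J", "C")))
  isCRvd <- anyTemplate(list("V", c("V", "D"))) && tail <= th$tail_max
  isPR <- anyTemplate(list(c("D", "J"), c("D", "J", "C"))) &&
    intron >= th$intron_min
  isPRdOnly <- identical(kinds, "D") && tail > 0L
  isIJC <- anyTemplate(list(c("I", "J"), c("I", "J", "C")))
  isAR <- isIJC && !is.na(rss) && rss <= th$rss_window
  hasXCjoin <- length(kinds) > 1L &&
    any(kinds[-length(kinds)] %in% c("V", "D", "I") & kinds[-1L] == "C")
  isAS <- hasXCjoin || isIJC
  isNR <- anyTemplate(list("J", c("J", "C"))) && intron >= th$intron_min
  isNS <- identical(kinds, "C") && intron >= th$intron_min &&
    head <= th$c_unaligned_max && tail <= th$c_unaligned_max
  if (isCH) "CH"
  else if (isCRfull || isCRvd) "CR"
  else if (isPR || isPRdOnly) "PR"
  else if (isAR) "AR"
  else if (isAS) "AS"
  else if (isNR) "NR"
  else if (isNS) "NS"
  else "UC"
}

## all kind templates of length 1..maxLen over {V, D, J, C, I}
allKindTemplates <- function(maxLen = 4L) {
  alph <- c("V", "D", "J", "C", "I")
  out <- list()
  for (len in seq_len(maxLen)) {
    grid <- do.call(expand.grid,
                    c(rep(list(alph), len), stringsAsFactors = FALSE))
    out <- c(out, lapply(seq_len(nrow(grid)), function(i) {
      unname(unlist(grid[i, ]))
    }))
  }
  out
}

## --- chain-selection oracle ------------------------------------------------
## exhaustive subset enumeration with the documented tie-breaks
oracleChain <- function(segs) {
  segs <- segs[order(segs$read_start, segs$read_end), , drop = FALSE]
  n <- nrow(segs)
  best <- NULL
  for (mask in seq_len(2^n - 1L)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0L)
    str <- unique(segs$strand[idx])
    if (length(str) > 1L) next
    ok <- TRUE
    if (length(idx) > 1L) {
      for (q in seq_len(length(idx) - 1L)) {
        a <- idx[q]; b <- idx[q + 1L]
        if (segs$read_start[b] <= segs$read_end[a]) { ok <- FALSE; break }
        mono <- if (str == "+") segs$ref_start[b] > segs$ref_start[a]
                else segs$ref_start[b] < segs$ref_start[a]
        if (!mono) { ok <- FALSE; break }
      }
    }
    if (!ok) next
    cand <- list(idx = idx,
                 score = sum(segs$read_end[idx] - segs$read_start[idx] + 1L),
                 nseg = length(idx), start = segs$read_start[idx[1L]],
                 strand = str)
    replace <- is.null(best) || cand$score > best$score ||
      (cand$score == best$score && cand$nseg > best$nseg) ||
      (cand$score == best$score && cand$nseg == best$nseg &&
         cand$start < best$start) ||
      (cand$score == best$score && cand$nseg == best$nseg &&
         cand$start == best$start && cand$strand == "+" && best$strand != "+")
    if (replace) best <- cand
  }
  best
}

## random segment set for chain-oracle tests; quantised lengths force ties
randomSegs <- function(n) {
  len <- sample(c(20L, 40L, 60L), n, replace = TRUE)
  rs <- sample(1:250, n)
  fs <- sample(1:3000, n)
  mkSeg(rs, rs + len - 1L, fs, fs + len - 1L,
        strand = sample(c("+", "-"), n, replace = TRUE, prob = c(0.8, 0.2)))
}

## --- exact Wilcoxon oracle -------------------------------------------------
## enumerates all C(nA+nB, nA) rank assignments
bruteWilcoxP <- function(a, b) {
  nA <- length(a); nB <- length(b)
  r <- rank(c(a, b))
  obs <- sum(r[seq_len(nA)])
  sums <- apply(utils::combn(nA + nB, nA), 2L,
                function(ii) sum(r[ii]))
  pLo <- mean(sums <= obs)
  pHi <- mean(sums >= obs)
  min(1, 2 * min(pLo, pHi))
}

## --- primer-mapping oracle -------------------------------------------------
## all-window Hamming scan of one primer over both strands
brutePrimerHits <- function(primerSeq, locusStr, maxMismatch = 4L) {
  n <- nchar(locusStr); k <- nchar(primerSeq)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(primerSeq)))
  out <- list()
  for (str in c("+", "-")) {
    pat <- strsplit(if (str == "+") primerSeq else rc, "")[[1L]]
    wins <- substring(locusStr, 1:(n - k + 1L), k:n)
    mm <- vapply(wins, function(w) {
      sum(strsplit(w, "")[[1L]] != pat)
    }, integer(1), USE.NAMES = FALSE)
    hit <- which(mm <= maxMismatch)
    if (length(hit)) {
      out[[str]] <- data.frame(ref_start = hit, ref_end = hit + k - 1L,
                               strand = str, mismatches = mm[hit],
                               stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
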