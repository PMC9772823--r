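## De-multiplexing, technical-sequence trimming and the length filter.

## vectorized Hamming distances between equal-width read substrings and one
## reference oligo; substrings containing non-ACGT count as mismatches there
.oligoDist <- function(strings, oligo) {
  k <- nchar(oligo)
  out <- rep(NA_integer_, length(strings))
  ok <- !is.na(strings) & nchar(strings) == k
  if (any(ok)) {
    m <- do.call(rbind, strsplit(strings[ok], ""))
    ref <- strsplit(oligo, "")[[1L]]
    out[ok] <- as.integer(rowSums(m != matrix(ref, nrow(m), k, byrow = TRUE)))
  }
  out
}

## best matching barcode per string: list(sample, mismatches)
.callBarcode <- function(strings, barcodeMap, maxMismatch = 2L) {
  d <- vapply(barcodeMap$barcode, function(b) .oligoDist(strings, b),
              integer(length(strings)))
  if (is.null(dim(d))) d <- matrix(d, nrow = length(strings))
  best <- apply(d, 1L, function(r) {
    if (all(is.na(r))) return(c(NA_integer_, NA_integer_))
    i <- which.min(r)
    c(i, r[i])
  })
  sample <- barcodeMap$sample_id[best[1L, ]]
  mm <- best[2L, ]
  sample[is.na(mm) | mm > maxMismatch] <- NA_character_
  list(sample = sample, mismatches = mm)
}

#' Locate technical sequences (adapters, barcodes, UPM) on raw reads
#'
#' Finds, per read end, the adaptor (allowing ~10% mismatches),
#' the adjacent 10 bp barcode (called against the barcode map when at least
#' 8 of 10 bases match) and, at the 5' end, the universal primer. The 3'
#' adaptor and barcode are searched reverse-complemented, as they are read
#' on the opposite strand.
#'
#' @param reads named [Biostrings::DNAStringSet] (or character vector) of
#'   raw reads
#' @param barcodeMap data.frame with `sample_id`, `barcode`
#' @param adapters list as from [defaultAdapters()]
#' @param maxAdapterMismatch mismatch budget for each 25 bp adaptor
#' @param maxBarcodeMismatch mismatch budget for a 10 bp barcode call
#' @return data.frame with one row per read: `read_id`, `bc5_sample`,
#'   `bc5_mm`, `bc3_sample`, `bc3_mm`, `tech5_end`, `tech3_start`
#'   (innermost technical boundaries; `NA` when that end had no detectable
#'   technical sequence)
#' @export
findTechnical <- function(reads, barcodeMap, adapters = defaultAdapters(),
                          maxAdapterMismatch = 3L, maxBarcodeMismatch = 2L) {
  if (!is(reads, "DNAStringSet")) reads <- DNAStringSet(reads)
  if (is.null(names(reads))) names(reads) <- sprintf("read%06d", seq_along(reads))
  rs <- as.character(reads)
  L <- nchar(rs)
  n <- length(rs)

  ## 5' adaptor
  m1 <- Biostrings::vmatchPattern(adapters$adapter1, reads,
                                  max.mismatch = maxAdapterMismatch)
  a1end <- vapply(seq_len(n), function(i) {
    h <- m1[[i]]
    h <- h[start(h) <= 6L]
    if (length(h)) end(h)[1L] else NA_integer_
  }, integer(1))

  ## 3' adaptor (reverse-complemented in read orientation)
  rcA2 <- .revcomp(adapters$adapter2)
  m2 <- Biostrings::vmatchPattern(rcA2, reads,
                                  max.mismatch = maxAdapterMismatch)
  a2start <- vapply(seq_len(n), function(i) {
    h <- m2[[i]]
    h <- h[end(h) >= L[i] - 5L]
    if (length(h)) start(h)[length(h)] else NA_integer_
  }, integer(1))

  bc5seq <- ifelse(is.na(a1end), NA_character_,
                   substr(rs, a1end + 1L, a1end + 10L))
  bc5 <- .callBarcode(bc5seq, barcodeMap, maxBarcodeMismatch)

  bc3raw <- ifelse(is.na(a2start), NA_character_,
                   substr(rs, a2start - 10L, a2start - 1L))
  bc3seq <- ifelse(is.na(bc3raw), NA_character_, .revcompSafe(bc3raw))
  bc3 <- .callBarcode(bc3seq, barcodeMap, maxBarcodeMismatch)

  ## universal primer after the 5' barcode
  upmLen <- nchar(adapters$upm)
  upmSeq <- ifelse(is.na(a1end), NA_character_,
                   substr(rs, a1end + 11L, a1end + 10L + upmLen))
  upmMM <- .oligoDist(upmSeq, adapters$upm)
  tech5End <- ifelse(is.na(a1end), NA_integer_,
                     ifelse(!is.na(upmMM) & upmMM <= ceiling(0.1 * upmLen),
                            a1end + 10L + upmLen, a1end + 10L))
  tech3Start <- ifelse(is.na(a2start), NA_integer_, a2start - 10L)

  data.frame(read_id = names(reads),
             bc5_sample = bc5$sample, bc5_mm = bc5$mismatches,
             bc3_sample = bc3$sample, bc3_mm = bc3$mismatches,
             tech5_end = tech5End, tech3_start = tech3Start,
             read_length = L, stringsAsFactors = FALSE)
}

## vectorized reverse complement tolerating NA
.revcompSafe <- function(x) {
  out <- rep(NA_character_, length(x))
  ok <- !is.na(x)
  if (any(ok)) {
    out[ok] <- as.character(reverseComplement(DNAStringSet(x[ok])))
  }
  out
}

#' Assign reads to samples from their end barcodes
#'
#' A read is assigned when the best barcode at both ends names the same
#' sample. Reads whose two ends name different samples are discarded
#' (reason `"inconsistent_barcodes"`). Reads with only one detectable end
#' barcode are assigned to that sample by default (set
#' `requireBothEnds = TRUE` to discard them); reads with no detectable
#' barcode are discarded (reason `"no_barcode"`).
#'
#' @param tech data.frame from [findTechnical()]
#' @param requireBothEnds require consistent barcodes on both ends
#' @return `tech` with added columns `sample_id` (NA when discarded) and
#'   `demux_reason` (`"both_ends"`, `"single_end"`,
#'   `"inconsistent_barcodes"`, `"no_barcode"`)
#' @export
demultiplex <- function(tech, requireBothEnds = FALSE) {
  b5 <- tech$bc5_sample; b3 <- tech$bc3_sample
  sample <- rep(NA_character_, nrow(tech))
  reason <- rep(NA_character_, nrow(tech))

  both <- !is.na(b5) & !is.na(b3)
  agree <- both & b5 == b3
  sample[agree] <- b5[agree]
  reason[agree] <- "both_ends"
  reason[both & !agree] <- "inconsistent_barcodes"

  single <- xor(!is.na(b5), !is.na(b3))
  reason[single] <- "single_end"
  if (!requireBothEnds) {
    sample[single] <- ifelse(!is.na(b5[single]), b5[single], b3[single])
  }
  none <- is.na(b5) & is.na(b3)
  reason[none] <- "no_barcode"

  tech$sample_id <- sample
  tech$demux_reason <- reason
  tech
}

#' Trim technical sequences and apply the length filter
#'
#' Retains the interior sequence between the innermost technical spans and
#' keeps it iff its length is at least `minLen` (the boundary: 150 bp kept,
#' 149 bp dropped). Reads that are technical sequence only are discarded
#' with reason `"no_insert"`.
#'
#' @param reads the raw reads given to [findTechnical()]
#' @param tech data.frame from [demultiplex()]
#' @param minLen minimum trimmed length (default 150)
#' @return list with `processed` (data.frame `read_id`, `sample_id`,
#'   `sequence`, `trim_start`, `trim_end`) and `discarded` (data.frame
#'   `read_id`, `reason`)
#' @export
trimAndFilter <- function(reads, tech, minLen = 150L) {
  if (!is(reads, "DNAStringSet")) reads <- DNAStringSet(reads)
  rs <- as.character(reads)[tech$read_id]
  L <- nchar(rs)
  from <- ifelse(is.na(tech$tech5_end), 1L, tech$tech5_end + 1L)
  to <- ifelse(is.na(tech$tech3_start), L, tech$tech3_start - 1L)

  assigned <- !is.na(tech$sample_id)
  noInsert <- from > to
  seqs <- ifelse(noInsert, "", substr(rs, from, to))
  tooShort <- nchar(seqs) < minLen

  keep <- assigned & !noInsert & !tooShort
  reason <- rep(NA_character_, nrow(tech))
  reason[!assigned] <- tech$demux_reason[!assigned]
  reason[assigned & noInsert] <- "no_insert"
  reason[assigned & !noInsert & tooShort] <- "too_short"

  list(
    processed = data.frame(read_id = tech$read_id[keep],
                           sample_id = tech$sample_id[keep],
                           sequence = seqs[keep],
                           trim_start = from[keep], trim_end = to[keep],
                           stringsAsFactors = FALSE),
    discarded = data.frame(read_id = tech$read_id[!keep],
                           reason = reason[!keep],
                           stringsAsFactors = FALSE)
  )
}

#' Full preprocessing: demultiplex, trim, filter
#'
#' Convenience wrapper running [findTechnical()], [demultiplex()] and
#' [trimAndFilter()]. The reason-code ledger satisfies count conservation:
#' `nrow(processed) + nrow(discarded) == length(reads)`.
#'
#' @inheritParams findTechnical
#' @inheritParams demultiplex
#' @inheritParams trimAndFilter
#' @return list with `processed`, `discarded` (see [trimAndFilter()]) and
#'   `tech` (the per-read technical report)
#' @export
preprocessReads <- function(reads, barcodeMap, adapters = defaultAdapters(),
                            minLen = 150L, requireBothEnds = FALSE) {
  tech <- findTechnical(reads, barcodeMap, adapters)
  tech <- demultiplex(tech, requireBothEnds = requireBothEnds)
  out <- trimAndFilter(reads, tech, minLen = minLen)
  out$tech <- tech
  out
}
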