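#' @import methods
#' @importFrom S4Vectors mcols mcols<- DataFrame
#' @importFrom IRanges IRanges
#' @importFrom GenomicRanges GRanges seqnames start end width strand
#' @importFrom Biostrings DNAString DNAStringSet subseq reverseComplement
NULL

#' TcrbLocus: an annotated TCR-beta-like reference locus
#'
#' Container for a single contiguous TCRB(-like) reference sequence together
#' with its typed gene-segment annotation, planted splice motifs and
#' (cryptic) recombination signal sequence (RSS) sites. All downstream
#' stages -- read simulation, alignment, chain post-processing and category
#' classification -- consume this object.
#'
#' Coordinates are 1-based and closed (the IRanges convention). A splice
#' *donor* at position `p` means the dinucleotide `GT` occupies `p+1..p+2`
#' (`p` is the last exonic base); a splice *acceptor* at position `p` means
#' `AG` occupies `p-2..p-1` (`p` is the first exonic base).
#'
#' @slot sequence [Biostrings::DNAString] reference sequence.
#' @slot segments [GenomicRanges::GRanges] gene segments, with metadata
#'   columns `name` (unique), `kind` (one of `"V"`, `"D"`, `"J"`, `"C"`,
#'   `"pseudo-J"`) and `functional` (logical).
#' @slot spliceSites [GenomicRanges::GRanges] width-1 positions with a
#'   metadata column `role` (`"donor"` or `"acceptor"`).
#' @slot rssSites [GenomicRanges::GRanges] RSS motifs with metadata columns
#'   `spacer` (12 or 23) and `cryptic` (logical).
#' @slot seqname single seqname used in all the GRanges slots and in
#'   FASTA/GFF3 output.
#'
#' @seealso [buildSyntheticLocus()], [readLocus()], [writeLocus()]
#' @export
setClass("TcrbLocus",
  representation(
    sequence    = "DNAString",
    segments    = "GRanges",
    spliceSites = "GRanges",
    rssSites    = "GRanges",
    seqname     = "character"
  )
)

.validTcrbLocus <- function(object) {
  msg <- character()
  s <- as.character(object@sequence)
  n <- nchar(s)
  seg <- object@segments
  if (length(seg) == 0L) {
    return("locus has no gene segments")
  }
  nm <- mcols(seg)$name
  kind <- mcols(seg)$kind
  if (anyDuplicated(nm)) {
    msg <- c(msg, "segment names are not unique")
  }
  if (!all(kind %in% c("V", "D", "J", "C", "pseudo-J"))) {
    msg <- c(msg, "segment kind must be V, D, J, C or pseudo-J")
  }
  o <- order(start(seg))
  st <- start(seg)[o]; en <- end(seg)[o]
  if (any(st > en)) msg <- c(msg, "segment interval start > end")
  if (any(en > n) || any(st < 1L)) msg <- c(msg, "segment outside locus bounds")
  if (length(seg) > 1L && any(st[-1L] <= en[-length(en)])) {
    msg <- c(msg, "gene segments overlap")
  }
  ## inter-segment gaps must leave room for the >=15 bp intron rules
  gaps <- st[-1L] - en[-length(en)] - 1L
  if (length(gaps) && any(gaps < 30L)) {
    msg <- c(msg, "minimum intron gap between segments is 30 bp")
  }
  ## segment ordering: V cluster, then D1/J1-cluster/C1, then D2/J2-cluster/C2
  ko <- kind[o]
  ko2 <- ifelse(ko == "pseudo-J", "J", ko)
  pat <- rle(ko2)$values
  if (!identical(pat, c("V", "D", "J", "C", "D", "J", "C"))) {
    msg <- c(msg, paste0(
      "segment kinds must follow V+, D, J+, C, D, J+, C order (got ",
      paste(pat, collapse = "-"), ")"))
  }
  ## a pseudo-J must sit immediately upstream of a functional J
  ps <- which(ko == "pseudo-J")
  if (length(ps) && any(ps == length(ko) | ko[pmin(ps + 1L, length(ko))] != "J")) {
    msg <- c(msg, "each pseudo-J must be immediately upstream of a J segment")
  }
  ## the two C segments must be near-identical (1-3 differing positions)
  ci <- o[ko == "C"]
  if (length(ci) == 2L) {
    c1 <- substring(s, start(seg)[ci[1L]], end(seg)[ci[1L]])
    c2 <- substring(s, start(seg)[ci[2L]], end(seg)[ci[2L]])
    if (nchar(c1) == nchar(c2)) {
      nd <- sum(strsplit(c1, "")[[1L]] != strsplit(c2, "")[[1L]])
      if (nd < 1L || nd > 3L) {
        msg <- c(msg, sprintf("C1 and C2 must differ at 1-3 positions (differ at %d)", nd))
      }
    } else {
      msg <- c(msg, "C1 and C2 must have equal length")
    }
  }
  ## splice motif check against the sequence
  ss <- object@spliceSites
  if (length(ss)) {
    p <- start(ss); role <- mcols(ss)$role
    don <- role == "donor"
    bad <- (don & substring(s, p + 1L, p + 2L) != "GT") |
           (!don & substring(s, p - 2L, p - 1L) != "AG")
    if (any(bad)) msg <- c(msg, "splice site without GT/AG motif in sequence")
  }
  rss <- object@rssSites
  if (length(rss) && (any(start(rss) < 1L) || any(end(rss) > n))) {
    msg <- c(msg, "RSS site outside locus bounds")
  }
  if (length(msg)) msg else TRUE
}

setValidity("TcrbLocus", .validTcrbLocus)

#' @describeIn TcrbLocus compact summary of the locus
#' @param object a `TcrbLocus`
#' @export
setMethod("show", "TcrbLocus", function(object) {
  seg <- object@segments
  kind <- mcols(seg)$kind
  cat("TcrbLocus (", object@seqname, "): ",
      length(object@sequence), " bp\n", sep = "")
  cat("  segments: ", length(seg),
      " (V:", sum(kind == "V"), " D:", sum(kind == "D"),
      " J:", sum(kind == "J"), " pseudo-J:", sum(kind == "pseudo-J"),
      " C:", sum(kind == "C"), ")\n", sep = "")
  cat("  splice sites: ", length(object@spliceSites),
      "; RSS sites: ", length(object@rssSites),
      " (cryptic: ", sum(mcols(object@rssSites)$cryptic %in% TRUE), ")\n",
      sep = "")
})

#' Accessors for TcrbLocus slots
#'
#' `locusSequence()` returns the reference [Biostrings::DNAString];
#' `geneSegments()`, `spliceSites()` and `rssSites()` return the annotation
#' [GenomicRanges::GRanges]; `locusLength()` the sequence length.
#'
#' @param x a [TcrbLocus-class] object
#' @return see description
#' @export
locusSequence <- function(x) {
  stopifnot(is(x, "TcrbLocus"))
  x@sequence
}

#' @rdname locusSequence
#' @export
geneSegments <- function(x) {
  stopifnot(is(x, "TcrbLocus"))
  x@segments
}

#' @rdname locusSequence
#' @export
spliceSites <- function(x) {
  stopifnot(is(x, "TcrbLocus"))
  x@spliceSites
}

#' @rdname locusSequence
#' @export
rssSites <- function(x) {
  stopifnot(is(x, "TcrbLocus"))
  x@rssSites
}

#' @rdname locusSequence
#' @export
locusLength <- function(x) {
  stopifnot(is(x, "TcrbLocus"))
  length(x@sequence)
}

## internal: segment annotation as a plain data.frame (fast row access)
.segTable <- function(locus) {
  seg <- locus@segments
  data.frame(
    name = mcols(seg)$name,
    kind = mcols(seg)$kind,
    functional = mcols(seg)$functional,
    start = start(seg),
    end = end(seg),
    stringsAsFactors = FALSE
  )[order(start(seg)), , drop = FALSE]
}

## internal: sequence of a named segment
.segSeq <- function(locus, name) {
  tab <- .segTable(locus)
  i <- match(name, tab$name)
  if (is.na(i)) stop("unknown segment name: ", name)
  substring(as.character(locus@sequence), tab$start[i], tab$end[i])
}
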