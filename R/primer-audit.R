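## Mapping multiplex-PCR primers onto the locus and assessing variants in
## primer binding sites.

#' Map primer oligos onto the locus
#'
#' Ungapped sliding-window alignment of each primer on both strands of the
#' locus, keeping placements with at most `maxMismatch` mismatches. For
#' each gene segment, the best hit overlapping the segment is retained
#' (fewest mismatches; ties resolved to the leftmost placement, then the
#' first primer in input order); segments without any hit are reported
#' unmapped.
#'
#' @param primers data.frame with columns `primer_id`, `seq` (15-30 nt)
#' @param locus a [TcrbLocus-class]
#' @param maxMismatch mismatch budget (default 4)
#' @param kinds segment kinds to audit (default V and J)
#' @return list with `hits` (one row per mapped segment: `segment_name`,
#'   `primer_id`, `ref_start`, `ref_end`, `strand`, `mismatches`,
#'   `mismatch_offsets_3p` comma-separated offsets of mismatched bases
#'   from the primer 3' end) and `unmapped` (segment names)
#' @export
mapPrimers <- function(primers, locus, maxMismatch = 4L,
                       kinds = c("V", "J")) {
  stopifnot(all(c("primer_id", "seq") %in% names(primers)))
  if (any(nchar(primers$seq) < 15L | nchar(primers$seq) > 30L)) {
    stop("primer lengths must be 15-30 nt")
  }
  s <- locusSequence(locus)
  allHits <- list()
  for (i in seq_len(nrow(primers))) {
    pseq <- primers$seq[i]
    for (str in c("+", "-")) {
      pat <- if (str == "+") pseq else .revcomp(pseq)
      m <- Biostrings::matchPattern(pat, s, max.mismatch = maxMismatch)
      if (!length(m)) next
      mm <- Biostrings::neditStartingAt(DNAString(pat), s, starting.at = start(m))
      allHits[[length(allHits) + 1L]] <- data.frame(
        primer_id = primers$primer_id[i], primer_seq = pseq,
        ref_start = start(m), ref_end = end(m), strand = str,
        mismatches = mm, order = i, stringsAsFactors = FALSE)
    }
  }
  tab <- .segTable(locus)
  tab <- tab[tab$kind %in% kinds, , drop = FALSE]
  hits <- if (length(allHits)) do.call(rbind, allHits) else NULL

  rows <- list(); unmapped <- character()
  for (k in seq_len(nrow(tab))) {
    if (is.null(hits)) { unmapped <- c(unmapped, tab$name[k]); next }
    ov <- hits[hits$ref_start <= tab$end[k] & hits$ref_end >= tab$start[k], ,
               drop = FALSE]
    if (nrow(ov) == 0L) { unmapped <- c(unmapped, tab$name[k]); next }
    ov <- ov[order(ov$mismatches, ov$ref_start, ov$order), , drop = FALSE]
    best <- ov[1L, ]
    off <- .mismatchOffsets3p(best, s)
    rows[[length(rows) + 1L]] <- data.frame(
      segment_name = tab$name[k], primer_id = best$primer_id,
      ref_start = best$ref_start, ref_end = best$ref_end,
      strand = best$strand, mismatches = best$mismatches,
      mismatch_offsets_3p = paste(off, collapse = ","),
      stringsAsFactors = FALSE)
  }
  hitsDf <- if (length(rows)) do.call(rbind, rows) else
    data.frame(segment_name = character(), primer_id = character(),
               ref_start = integer(), ref_end = integer(),
               strand = character(), mismatches = integer(),
               mismatch_offsets_3p = character(), stringsAsFactors = FALSE)
  rownames(hitsDf) <- NULL
  list(hits = hitsDf, unmapped = unmapped)
}

## offsets (3'-terminal base = 0) of mismatched positions of one hit
.mismatchOffsets3p <- function(hit, locusSeq) {
  ref <- strsplit(as.character(subseq(locusSeq, hit$ref_start, hit$ref_end)),
                  "")[[1L]]
  pat <- if (hit$strand == "+") hit$primer_seq else .revcomp(hit$primer_seq)
  pv <- strsplit(pat, "")[[1L]]
  bad <- which(pv != ref)
  if (!length(bad)) return(integer(0))
  ## primer 3' end sits at ref_end on "+", at ref_start on "-"
  if (hit$strand == "+") sort(length(pv) - bad) else sort(bad - 1L)
}

#' Assess a variant against a primer binding site
#'
#' Reports whether the variant position falls inside the primer hit, its
#' distance from the primer 3' end (3'-terminal base = 0), and whether the
#' alternate allele improves (`+1`), worsens (`-1`) or leaves unchanged
#' (`0`) the primer match relative to the reference allele.
#'
#' @param variant list or one-row data.frame with `position` (1-based
#'   locus coordinate), `ref_allele`, `alt_allele` (single bases)
#' @param hit one row of `mapPrimers()$hits`
#' @param primerSeq the primer sequence (5'->3')
#' @param locus a [TcrbLocus-class]
#' @return list with `in_site`, `dist_from_3prime`, `match_delta`
#' @export
assessVariant <- function(variant, hit, primerSeq, locus) {
  pos <- as.integer(variant$position)
  if (is.na(pos) || pos < 1L || pos > locusLength(locus)) {
    stop("variant position outside the locus")
  }
  inSite <- pos >= hit$ref_start && pos <= hit$ref_end
  if (!inSite) {
    return(list(in_site = FALSE, dist_from_3prime = NA_integer_,
                match_delta = 0L))
  }
  dist <- if (hit$strand == "+") hit$ref_end - pos else pos - hit$ref_start
  ## primer base expressed on the locus plus strand at the variant position
  if (hit$strand == "+") {
    pb <- substr(primerSeq, pos - hit$ref_start + 1L, pos - hit$ref_start + 1L)
  } else {
    pb <- .complementBase(substr(primerSeq, hit$ref_end - pos + 1L,
                                 hit$ref_end - pos + 1L))
  }
  ref <- toupper(variant$ref_allele); alt <- toupper(variant$alt_allele)
  delta <- if (pb == alt && pb != ref) 1L
           else if (pb == ref && pb != alt) -1L
           else 0L
  list(in_site = TRUE, dist_from_3prime = as.integer(dist),
       match_delta = delta)
}

#' Read a variant table
#'
#' Tab-separated SNP table with columns `position` (1-based), `ref_allele`,
#' `alt_allele` and one numeric frequency column per population.
#'
#' @param path TSV path
#' @return data.frame of variants
#' @export
readVariants <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("position", "ref_allele", "alt_allele")
  if (!all(need %in% names(d))) {
    stop("variant table must have columns: ", paste(need, collapse = ", "))
  }
  d
}

#' Filter variants by population allele frequency
#'
#' Retains a variant iff its maximum allele frequency over the named
#' populations is positive, annotating the retained variants with that
#' maximum. Missing population columns are treated as zero with a warning.
#'
#' @param variants data.frame with one numeric column per population
#' @param populations population column names to consider
#' @param segmentExclude optional character vector of `segment_name`s to
#'   drop before filtering (requires a `segment_name` column)
#' @return the retained variants with a `max_freq` column
#' @export
filterVariantsByFreq <- function(variants,
                                 populations = c("Asian", "East_Asian",
                                                 "Other_Asian"),
                                 segmentExclude = NULL) {
  if (!is.null(segmentExclude) && "segment_name" %in% names(variants)) {
    variants <- variants[!variants$segment_name %in% segmentExclude, ,
                         drop = FALSE]
  }
  missing <- setdiff(populations, names(variants))
  if (length(missing)) {
    warning("missing population column(s) treated as zero: ",
            paste(missing, collapse = ", "))
  }
  have <- intersect(populations, names(variants))
  if (!length(have)) {
    mx <- rep(0, nrow(variants))
  } else {
    m <- as.matrix(variants[, have, drop = FALSE])
    m[is.na(m)] <- 0
    mx <- apply(m, 1L, max)
  }
  out <- variants[mx > 0, , drop = FALSE]
  out$max_freq <- mx[mx > 0]
  rownames(out) <- NULL
  out
}
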