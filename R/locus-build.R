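## Synthetic TCRB-like locus construction and motif/RSS lookups.

## 5'RACE constant-region primers; the two differ at a single base of the
## 23 bp binding site, which is what makes C1/C2 annotation swappable.
TRB_C1_PRIMER <- "GGGTGGGAACACCTTGTTCAGGT"
TRB_C2_PRIMER <- "GGGTGGGAACACCTTTTTCAGGT"

## RSS consensus used for planted cryptic sites (heptamer + 23 bp spacer +
## nonamer)
RSS_HEPTAMER <- "CACAGTG"
RSS_NONAMER <- "ACAAAAACC"

#' Default configuration for the synthetic locus builder
#'
#' Returns the list of layout parameters consumed by
#' [buildSyntheticLocus()]. Lengths are in bp. The defaults give a ~5 kb
#' locus with five V segments, two D-J-C clusters (three J1 segments; J2-1,
#' the pseudogene J2-2P and J2-3 in the second cluster) and near-identical
#' C1/C2 segments differing at one base of the 23 bp constant-region primer
#' site. A cryptic 23RSS and an intergenic splice donor are planted upstream
#' of D1 (400 bp and 174 bp upstream, respectively), and a second intergenic
#' donor 150 bp upstream of D2.
#'
#' @return named list of layout parameters
#' @export
defaultLocusConfig <- function() {
  list(
    n_v = 5L,           # number of V segments (>= 2)
    v_len = 200L,       # V segment length; last primer_site_len bp act as a
                        # unique multiplex-primer binding site
    primer_site_len = 20L,
    d_len = 16L,        # D segment length
    j_len = 50L,        # J segment length
    n_j1 = 3L,          # J segments in the J1 cluster (>= 2)
    c_len = 130L,       # C segment length
    c_take = 100L,      # transcribed C prefix retained in simulated inserts
    margin = 100L,      # flanking sequence at both locus ends
    intron_v = 100L,    # intron after each V (except the last)
    gap_v_d1 = 600L,    # intergenic region between the last V and D1
    intron_d_j = 100L,  # intron between D and the first J of its cluster
    gap_j = 80L,        # gap between successive J segments
    gap_j22p_j23 = 40L, # gap between the pseudogene J2-2P and J2-3
    intron_j_c = 120L,  # intron between the last J of a cluster and its C
    gap_c1_d2 = 400L,   # intergenic region between C1 and D2
    rss_offset = 400L,  # cryptic 23RSS start, upstream of D1
    as_donor_offset = 174L,  # intergenic splice donor upstream of D1
    d2_donor_offset = 150L   # intergenic splice donor upstream of D2
  )
}

.checkLocusConfig <- function(cfg) {
  if (cfg$n_v < 2L) stop("config must request at least 2 V segments")
  if (cfg$n_j1 < 2L) stop("config must request at least 2 J segments per cluster")
  gaps <- c(intron_v = cfg$intron_v, gap_v_d1 = cfg$gap_v_d1,
            intron_d_j = cfg$intron_d_j, gap_j = cfg$gap_j,
            gap_j22p_j23 = cfg$gap_j22p_j23, intron_j_c = cfg$intron_j_c,
            gap_c1_d2 = cfg$gap_c1_d2)
  bad <- names(gaps)[gaps < 30L]
  if (length(bad)) {
    stop("minimum intron gap is 30 bp; violated by: ", paste(bad, collapse = ", "))
  }
  if (cfg$c_take < 100L || cfg$c_len < cfg$c_take) {
    stop("c_len >= c_take >= 100 required (primer window sits at C positions 78-100)")
  }
  if (cfg$rss_offset + 38L > cfg$gap_v_d1 - 30L) {
    stop("rss_offset does not fit in the V-D1 intergenic region")
  }
  if (cfg$as_donor_offset + 2L > cfg$gap_v_d1 ||
      cfg$as_donor_offset >= cfg$rss_offset - 39L) {
    stop("as_donor_offset must lie between the cryptic RSS and D1")
  }
  if (cfg$d2_donor_offset + 2L > cfg$gap_c1_d2) {
    stop("d2_donor_offset does not fit in the C1-D2 intergenic region")
  }
  invisible(cfg)
}

#' Build a synthetic annotated TCR-beta-like locus
#'
#' Constructs a random locus whose gene segments follow the canonical TCRB
#' order V..., D1, J1-cluster, C1, D2, J2-cluster, C2, with the pseudogene
#' J2-2P immediately upstream of J2-3. GT/AG splice motifs are planted after
#' every V and functional J (donors) and before every functional J and C
#' (acceptors); two extra intergenic donors (174 bp upstream of D1 and
#' `d2_donor_offset` upstream of D2) model recurrent aberrant-splicing
#' donors, and a cryptic 23RSS consensus is planted `rss_offset` bp upstream
#' of D1. C2 is a copy of C1 whose 23 bp constant-primer window differs at
#' one base, so that C1/C2 annotation swaps are realistic. Deterministic for
#' a fixed seed.
#'
#' @param config layout list as from [defaultLocusConfig()]; partial lists
#'   are completed with defaults
#' @param seed integer seed (the caller's RNG state is preserved)
#' @param seqname reference name used in FASTA/GFF3 output
#' @return a [TcrbLocus-class] object
#' @examples
#' locus <- buildSyntheticLocus(seed = 1)
#' locus
#' @export
buildSyntheticLocus <- function(config = list(), seed = 1L, seqname = "TRBsyn") {
  cfg <- defaultLocusConfig()
  cfg[names(config)] <- config
  .checkLocusConfig(cfg)

  .withSeed(seed, {
    segs <- list()
    cursor <- 0L
    addSeg <- function(name, kind, len, functional = TRUE) {
      segs[[length(segs) + 1L]] <<- data.frame(
        name = name, kind = kind, functional = functional,
        start = cursor + 1L, end = cursor + len, stringsAsFactors = FALSE)
      cursor <<- cursor + len
    }

    cursor <- cursor + cfg$margin
    for (i in seq_len(cfg$n_v)) {
      addSeg(paste0("V", i), "V", cfg$v_len)
      if (i < cfg$n_v) cursor <- cursor + cfg$intron_v
    }
    cursor <- cursor + cfg$gap_v_d1
    addSeg("D1", "D", cfg$d_len)
    cursor <- cursor + cfg$intron_d_j
    for (j in seq_len(cfg$n_j1)) {
      addSeg(paste0("J1-", j), "J", cfg$j_len)
      if (j < cfg$n_j1) cursor <- cursor + cfg$gap_j
    }
    cursor <- cursor + cfg$intron_j_c
    addSeg("C1", "C", cfg$c_len)
    cursor <- cursor + cfg$gap_c1_d2
    addSeg("D2", "D", cfg$d_len)
    cursor <- cursor + cfg$intron_d_j
    addSeg("J2-1", "J", cfg$j_len)
    cursor <- cursor + cfg$gap_j
    addSeg("J2-2P", "pseudo-J", cfg$j_len, functional = FALSE)
    cursor <- cursor + cfg$gap_j22p_j23
    addSeg("J2-3", "J", cfg$j_len)
    cursor <- cursor + cfg$intron_j_c
    addSeg("C2", "C", cfg$c_len)
    cursor <- cursor + cfg$margin

    seg <- do.call(rbind, segs)
    total <- cursor
    chars <- sample(.BASES, total, replace = TRUE)

    stamp <- function(at, s) {
      v <- strsplit(s, "")[[1L]]
      chars[at:(at + length(v) - 1L)] <<- v
    }

    ## C1 primer window at C positions 78..100 (reverse strand primer site)
    c1 <- seg[seg$name == "C1", ]
    c2 <- seg[seg$name == "C2", ]
    stamp(c1$start + 77L, .revcomp(TRB_C1_PRIMER))
    ## C2 = copy of C1 with the one-base primer-window difference
    chars[c2$start:c2$end] <- chars[c1$start:c1$end]
    stamp(c2$start + 77L, .revcomp(TRB_C2_PRIMER))

    ## splice motifs: donors after V and functional J ends, acceptors before
    ## functional J and C starts
    donors <- integer(); acceptors <- integer()
    for (i in seq_len(nrow(seg))) {
      if (seg$kind[i] == "V" || (seg$kind[i] == "J" && seg$functional[i])) {
        donors <- c(donors, seg$end[i])
      }
      if ((seg$kind[i] == "J" && seg$functional[i]) || seg$kind[i] == "C") {
        acceptors <- c(acceptors, seg$start[i])
      }
    }
    d1 <- seg[seg$name == "D1", ]
    d2 <- seg[seg$name == "D2", ]
    donors <- c(donors, d1$start - cfg$as_donor_offset,
                d2$start - cfg$d2_donor_offset)
    for (p in donors) stamp(p + 1L, "GT")
    for (p in acceptors) stamp(p - 2L, "AG")

    ## cryptic 23RSS consensus upstream of D1
    rssStart <- d1$start - cfg$rss_offset
    stamp(rssStart, paste0(RSS_HEPTAMER, .randDNA(23L), RSS_NONAMER))

    segGr <- GRanges(seqname, IRanges(seg$start, seg$end), strand = "+",
                     name = seg$name, kind = seg$kind,
                     functional = seg$functional)
    ssGr <- GRanges(seqname,
                    IRanges(c(donors, acceptors), width = 1L), strand = "+",
                    role = rep(c("donor", "acceptor"),
                               c(length(donors), length(acceptors))))
    rssGr <- GRanges(seqname, IRanges(rssStart, width = 39L), strand = "+",
                     spacer = 23L, cryptic = TRUE)

    new("TcrbLocus",
        sequence = DNAString(paste(chars, collapse = "")),
        segments = segGr, spliceSites = ssGr, rssSites = rssGr,
        seqname = seqname)
  })
}

#' Scan a locus for GT/AG splice motifs
#'
#' Returns every position of the locus with donor context (`GT` immediately
#' after the position) or acceptor context (`AG` immediately before the
#' position). By construction this is a superset of the planted
#' [spliceSites()] annotation.
#'
#' @param locus a [TcrbLocus-class]
#' @return a [GenomicRanges::GRanges] of width-1 positions with a `role`
#'   metadata column (`"donor"`/`"acceptor"`)
#' @export
scanSpliceMotifs <- function(locus) {
  stopifnot(is(locus, "TcrbLocus"))
  s <- locus@sequence
  gt <- Biostrings::matchPattern("GT", s)
  ag <- Biostrings::matchPattern("AG", s)
  donors <- start(gt) - 1L
  donors <- donors[donors >= 1L]
  acceptors <- end(ag) + 1L
  acceptors <- acceptors[acceptors <= length(s)]
  GRanges(locus@seqname,
          IRanges(c(donors, acceptors), width = 1L), strand = "+",
          role = rep(c("donor", "acceptor"),
                     c(length(donors), length(acceptors))))
}

#' Consensus scan for cryptic 23RSS motifs
#'
#' Optional convenience scan for heptamer `CACAGTG` + 23 (+/- 1) bp spacer +
#' nonamer `ACAAAAACC` with at most `maxMismatch` total mismatches over
#' heptamer and nonamer. Classification consumes the planted [rssSites()]
#' annotation only; this scan exists to audit the annotation.
#'
#' @param locus a [TcrbLocus-class]
#' @param maxMismatch mismatch budget over heptamer+nonamer
#' @return [GenomicRanges::GRanges] of candidate RSS motifs with `spacer`
#'   metadata
#' @export
scanCrypticRSS <- function(locus, maxMismatch = 2L) {
  stopifnot(is(locus, "TcrbLocus"))
  s <- locus@sequence
  hits <- list()
  for (spacer in 22:24) {
    pat <- DNAString(paste0(RSS_HEPTAMER, strrep("N", spacer), RSS_NONAMER))
    m <- Biostrings::matchPattern(pat, s, max.mismatch = maxMismatch,
                                  fixed = FALSE)
    if (length(m)) {
      hits[[length(hits) + 1L]] <- data.frame(start = start(m),
                                              end = end(m), spacer = spacer)
    }
  }
  if (!length(hits)) {
    return(GRanges(seqnames = character(), ranges = IRanges(), spacer = integer()))
  }
  h <- do.call(rbind, hits)
  GRanges(locus@seqname, IRanges(h$start, h$end), strand = "+",
          spacer = h$spacer)
}

#' Distance to the nearest downstream cryptic 23RSS
#'
#' Distance in bp from `position` to the start of the nearest cryptic 23RSS
#' at or downstream of `position`, or `NA` if the locus carries none
#' (an explicit "absent" result). Used by the aberrant-recombination rule,
#' which requires an intergenic read segment to end within 30 bp of a
#' cryptic 23RSS start.
#'
#' @param locus a [TcrbLocus-class]
#' @param position 1-based reference coordinate within the locus
#' @return non-negative integer distance, or `NA_integer_` when absent
#' @export
nearestCrypticRSS <- function(locus, position) {
  stopifnot(is(locus, "TcrbLocus"))
  if (length(position) != 1L || is.na(position) ||
      position < 1L || position > locusLength(locus)) {
    stop("position out of locus bounds")
  }
  rss <- locus@rssSites
  rss <- rss[mcols(rss)$cryptic %in% TRUE & mcols(rss)$spacer == 23L]
  d <- start(rss) - as.integer(position)
  d <- d[d >= 0L]
  if (!length(d)) NA_integer_ else min(d)
}

#' Write / read a locus as FASTA + GFF3
#'
#' `writeLocus()` writes `<prefix>.fasta` (single record) and
#' `<prefix>.gff3` with feature types `gene_segment` (attributes `name`,
#' `kind`, `functional`), `splice_site` (`role`) and `rss_site` (`spacer`,
#' `cryptic`). `readLocus()` reconstructs an equal [TcrbLocus-class] from
#' those two files.
#'
#' @param locus a [TcrbLocus-class]
#' @param prefix output path prefix
#' @return `writeLocus()` the prefix, invisibly; `readLocus()` a
#'   [TcrbLocus-class]
#' @export
writeLocus <- function(locus, prefix) {
  stopifnot(is(locus, "TcrbLocus"))
  fa <- DNAStringSet(locus@sequence)
  names(fa) <- locus@seqname
  Biostrings::writeXStringSet(fa, paste0(prefix, ".fasta"))

  seg <- locus@segments
  mcols(seg) <- DataFrame(type = "gene_segment",
                          name = mcols(seg)$name,
                          kind = mcols(seg)$kind,
                          functional = as.character(mcols(seg)$functional))
  ss <- locus@spliceSites
  mcols(ss) <- DataFrame(type = "splice_site", role = mcols(ss)$role)
  rss <- locus@rssSites
  mcols(rss) <- DataFrame(type = "rss_site",
                          spacer = as.character(mcols(rss)$spacer),
                          cryptic = as.character(mcols(rss)$cryptic))
  gr <- c(seg, ss, rss)
  rtracklayer::export(gr, paste0(prefix, ".gff3"), format = "gff3")
  invisible(prefix)
}

#' @rdname writeLocus
#' @export
readLocus <- function(prefix) {
  fa <- Biostrings::readDNAStringSet(paste0(prefix, ".fasta"))
  if (length(fa) != 1L) stop("locus FASTA must contain exactly one record")
  seqname <- sub("\\s.*$", "", names(fa)[1L])
  gr <- rtracklayer::import(paste0(prefix, ".gff3"), format = "gff3")
  type <- as.character(mcols(gr)$type)

  seg <- gr[type == "gene_segment"]
  segGr <- GRanges(seqname, IRanges(start(seg), end(seg)), strand = "+",
                   name = as.character(mcols(seg)$name),
                   kind = as.character(mcols(seg)$kind),
                   functional = as.logical(mcols(seg)$functional))
  ss <- gr[type == "splice_site"]
  ssGr <- GRanges(seqname, IRanges(start(ss), end(ss)), strand = "+",
                  role = as.character(mcols(ss)$role))
  rss <- gr[type == "rss_site"]
  rssGr <- GRanges(seqname, IRanges(start(rss), end(rss)), strand = "+",
                   spacer = as.integer(mcols(rss)$spacer),
                   cryptic = as.logical(mcols(rss)$cryptic))
  new("TcrbLocus", sequence = fa[[1L]], segments = segGr,
      spliceSites = ssGr, rssSites = rssGr, seqname = seqname)
}
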