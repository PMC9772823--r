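## Labelled 5'RACE/454-style read simulation over a synthetic locus.

#' The eight read categories
#'
#' Completely recombined (CR), partially recombined (PR), non-recombined
#' (NR), non-spliced (NS), aberrantly spliced (AS), aberrantly recombined
#' (AR), uncertain (UC) and chimeric (CH).
#' @export
TRB_CATEGORIES <- c("CR", "PR", "NR", "NS", "AS", "AR", "UC", "CH")

## 454 library technical sequences (5'RACE universal primer and the two
## emulsion-PCR adaptors)
TRB_ADAPTER1 <- "CGTATCGCCTCCCTCGCGCCATCAG"
TRB_ADAPTER2 <- "CTATGCGCCTTGCCAGCCCGCTCAG"
TRB_UPM <- "CTAATACGACTCACTATAGGGC"

#' Default technical sequences used by the simulator and preprocessor
#' @return list with `adapter1`, `adapter2`, `upm` character strings
#' @export
defaultAdapters <- function() {
  list(adapter1 = TRB_ADAPTER1, adapter2 = TRB_ADAPTER2, upm = TRB_UPM)
}

#' Default category mix for simulated cohorts
#'
#' Non-recombined reads form the plurality (about 40%), CR about 30%,
#' aberrant splicing clearly exceeds PR, and UC/CH jointly account for ~3%
#' of reads -- the qualitative profile of healthy-donor TCRB 5'RACE
#' repertoires.
#'
#' @return named numeric vector over [TRB_CATEGORIES] summing to 1
#' @export
defaultCategoryMix <- function() {
  c(CR = 0.30, PR = 0.06, NR = 0.41, NS = 0.06,
    AS = 0.13, AR = 0.01, UC = 0.02, CH = 0.01)
}

#' Per-base error model for simulated reads
#'
#' @param substitution_rate per-base substitution probability (0-0.2)
#' @param indel_rate per-base insertion/deletion probability (0-0.2)
#' @param seed optional seed making [applyErrors()] self-deterministic;
#'   when `NULL` the caller's RNG state is used
#' @return an object of class `trb_error_model`
#' @export
errorModel <- function(substitution_rate = 0, indel_rate = 0, seed = NULL) {
  if (substitution_rate < 0 || substitution_rate > 0.2 ||
      indel_rate < 0 || indel_rate > 0.2) {
    stop("error rates must lie in [0, 0.2]")
  }
  structure(list(substitution_rate = substitution_rate,
                 indel_rate = indel_rate, seed = seed),
            class = "trb_error_model")
}

## locus lookups used repeatedly by the simulator
.simInfo <- function(locus) {
  seg <- .segTable(locus)
  s <- as.character(locusSequence(locus))
  vs <- seg[seg$kind == "V", ]
  js <- seg[seg$kind == "J" & seg$functional, ]
  d1 <- seg[seg$name == "D1", ]
  d2 <- seg[seg$name == "D2", ]
  c1i <- which(seg$kind == "C")[1L]
  c2i <- which(seg$kind == "C")[2L]
  j1names <- js$name[js$end < seg$start[c1i]]
  j2names <- js$name[js$start > seg$end[c1i]]
  don <- start(spliceSites(locus))[mcols(spliceSites(locus))$role == "donor"]
  intergenicDon <- don[!don %in% seg$end]
  p1 <- max(intergenicDon[intergenicDon < d1$start])  # AS donor upstream of D1
  p2 <- max(intergenicDon[intergenicDon < d2$start & intergenicDon > seg$end[c1i]])
  rss <- rssSites(locus)
  rssStart <- start(rss)[mcols(rss)$cryptic %in% TRUE][1L]
  list(seq = s, seg = seg, vs = vs, js = js, d1 = d1, d2 = d2,
       c1 = seg[c1i, ], c2 = seg[c2i, ],
       j1names = j1names, j2names = j2names,
       p1 = p1, p2 = p2, rssStart = rssStart, cTake = 100L)
}

.ref <- function(info, from, to) substring(info$seq, from, to)

## J the cluster C for a J name
.clusterC <- function(info, jname) {
  if (jname %in% info$j1names) info$c1 else info$c2
}

#' Simulate one insert of a given category
#'
#' Constructs a transcript insert whose (perfect) alignment against the
#' locus satisfies the defining structural rule of its category: NR inserts
#' begin with >= 15 bp of intron upstream of a J; PR inserts with >= 15 bp
#' of intron upstream of a D; CR inserts are spliced V-(D)-J-C with 6-20
#' random junction bases; NS inserts are intron+C; AS inserts splice an
#' intergenic/V donor (by default the donor 174 bp upstream of D1) to a
#' C or J acceptor; AR inserts start in intergenic sequence ending within
#' 30 bp of the planted cryptic 23RSS and continue J-C; CH inserts carry
#' two C segments (C-J-C); UC inserts are J-C with < 15 bp upstream intron.
#'
#' Randomness uses the caller's RNG state ([simulateCohort()] seeds it).
#'
#' @param locus a [TcrbLocus-class] built by [buildSyntheticLocus()]
#' @param category one of [TRB_CATEGORIES]
#' @param info optional precomputed `.simInfo(locus)` (internal speed-up)
#' @param asRandomDonorProb probability that an AS I-C insert ends at a
#'   random intergenic position instead of a planted GT donor
#' @return list with `seq` (insert string) and `truth` (list of category,
#'   subtype, segment names, cdr3_seq and donor evidence)
#' @export
simulateInsert <- function(locus, category, info = NULL,
                           asRandomDonorProb = 0) {
  if (!category %in% TRB_CATEGORIES) stop("unknown category: ", category)
  if (is.null(info)) info <- .simInfo(locus)
  truth <- list(category = category, subtype = NA_character_,
                v_name = NA_character_, d_name = NA_character_,
                j_name = NA_character_, c_name = NA_character_,
                cdr3_seq = NA_character_, donor_planted = NA)
  cT <- info$cTake
  cseq <- function(crow) .ref(info, crow$start, crow$start + cT - 1L)
  jrow <- function(nm) info$js[info$js$name == nm, ]

  seqs <- switch(category,
    CR = {
      v <- info$vs[sample.int(nrow(info$vs), 1L), ]
      withD <- runif(1) < 0.5
      if (withD) {
        cl <- sample(1:2, 1L)
        d <- if (cl == 1L) info$d1 else info$d2
        jn <- sample(if (cl == 1L) info$j1names else info$j2names, 1L)
      } else {
        d <- NULL
        jn <- sample(info$js$name, 1L)
      }
      j <- jrow(jn)
      cc <- .clusterC(info, jn)
      vTake <- sample(80:(v$end - v$start + 1L), 1L)
      cdr3 <- if (withD) {
        paste0(.randDNA(sample(3:10, 1L)),
               .ref(info, d$start, d$end),
               .randDNA(sample(3:10, 1L)))
      } else .randDNA(sample(6:20, 1L))
      truth$v_name <- v$name
      truth$d_name <- if (withD) d$name else NA_character_
      truth$j_name <- jn; truth$c_name <- cc$name
      truth$cdr3_seq <- cdr3
      truth$subtype <- "V-(D)-J-(C)"
      paste0(.ref(info, v$end - vTake + 1L, v$end), cdr3,
             .ref(info, j$start, j$end), cseq(cc))
    },
    PR = {
      cl <- sample(1:2, 1L)
      d <- if (cl == 1L) info$d1 else info$d2
      jn <- sample(if (cl == 1L) info$j1names else info$j2names, 1L)
      j <- jrow(jn); cc <- .clusterC(info, jn)
      intron <- sample(15:80, 1L)
      junc <- .randDNA(sample(0:10, 1L))
      truth$d_name <- d$name; truth$j_name <- jn; truth$c_name <- cc$name
      truth$subtype <- "D-J-(C)"
      paste0(.ref(info, d$start - intron, d$end), junc,
             .ref(info, j$start, j$end), cseq(cc))
    },
    NR = {
      ## J usage skewed toward J2-3; its upstream intron covers the
      ## pseudogene J2-2P for ~76.2% of J2-3 reads
      pj <- ifelse(info$js$name == "J2-3", 0.7,
                   0.3 / (nrow(info$js) - 1L))
      jn <- sample(info$js$name, 1L, prob = pj)
      j <- jrow(jn); cc <- .clusterC(info, jn)
      if (jn == "J2-3") {
        covers <- runif(1) < 0.762
        intron <- if (covers) sample(46:130, 1L) else sample(15:35, 1L)
        truth$subtype <- if (covers) "J2-2P~J2-3" else "J2-3_only"
      } else {
        intron <- sample(15:75, 1L)
        truth$subtype <- "other-J"
      }
      truth$j_name <- jn; truth$c_name <- cc$name
      paste0(.ref(info, j$start - intron, j$end), cseq(cc))
    },
    NS = {
      cc <- if (runif(1) < 0.5) info$c1 else info$c2
      intron <- sample(50:110, 1L)
      truth$c_name <- cc$name; truth$subtype <- "C-only"
      .ref(info, cc$start - intron, cc$start + cT - 1L)
    },
    AS = {
      sub <- sample(c("I-C", "V-C", "I-J-(C)"), 1L,
                    prob = c(0.7, 0.15, 0.15))
      truth$subtype <- sub
      if (sub == "I-C") {
        len <- sample(60:200, 1L)
        planted <- runif(1) >= asRandomDonorProb
        endPos <- if (planted) info$p1 else
          info$p1 - sample(5:40, 1L)  # random non-donor end nearby
        truth$donor_planted <- planted
        truth$c_name <- info$c1$name
        paste0(.ref(info, endPos - len + 1L, endPos), cseq(info$c1))
      } else if (sub == "V-C") {
        v <- info$vs[sample.int(nrow(info$vs), 1L), ]
        vTake <- sample(80:(v$end - v$start + 1L), 1L)
        truth$v_name <- v$name; truth$c_name <- info$c1$name
        truth$donor_planted <- TRUE
        paste0(.ref(info, v$end - vTake + 1L, v$end), cseq(info$c1))
      } else {
        len <- sample(60:140, 1L)
        jn <- sample(info$j2names, 1L)
        j <- jrow(jn)
        truth$j_name <- jn; truth$c_name <- info$c2$name
        truth$donor_planted <- TRUE
        paste0(.ref(info, info$p2 - len + 1L, info$p2),
               .ref(info, j$start, j$end), cseq(info$c2))
      }
    },
    AR = {
      d <- sample(3:25, 1L)
      len <- sample(60:150, 1L)
      endPos <- info$rssStart - d
      jn <- sample(info$js$name, 1L)
      j <- jrow(jn); cc <- .clusterC(info, jn)
      truth$j_name <- jn; truth$c_name <- cc$name
      truth$subtype <- "I-J-(C)"
      paste0(.ref(info, endPos - len + 1L, endPos),
             .ref(info, j$start, j$end), cseq(cc))
    },
    UC = {
      jn <- sample(info$js$name, 1L)
      j <- jrow(jn); cc <- .clusterC(info, jn)
      intron <- sample(0:14, 1L)
      truth$j_name <- jn; truth$c_name <- cc$name
      truth$subtype <- "J-(C) short intron"
      paste0(.ref(info, j$start - intron, j$end), cseq(cc))
    },
    CH = {
      j <- jrow("J2-3")
      truth$j_name <- "J2-3"; truth$c_name <- "C1+C2"
      truth$subtype <- "C-J-C"
      paste0(cseq(info$c1), .ref(info, j$start, j$end), cseq(info$c2))
    }
  )
  list(seq = seqs, truth = truth)
}

#' Attach technical sequences to an insert
#'
#' Builds the raw read `adapter1 + barcode + UPM + insert +
#' revcomp(barcode) + revcomp(adapter2)`: the 3' barcode/adaptor are
#' sequenced on the opposite strand and therefore appear
#' reverse-complemented in read orientation.
#'
#' @param insert insert nucleotide string (may be empty)
#' @param barcode 10 bp sample barcode
#' @param adapters list as from [defaultAdapters()]
#' @return list with `read` (string) and `insert_coords`
#'   (`c(start, end)` of the insert within the read; `NULL` insert gives a
#'   zero-width placeholder)
#' @export
attachTechnical <- function(insert, barcode, adapters = defaultAdapters()) {
  if (nchar(barcode) != 10L) stop("barcode must be exactly 10 bp")
  head <- paste0(adapters$adapter1, barcode, adapters$upm)
  tail <- paste0(.revcomp(barcode), .revcomp(adapters$adapter2))
  list(read = paste0(head, insert, tail),
       insert_coords = c(start = nchar(head) + 1L,
                         end = nchar(head) + nchar(insert)))
}

#' Apply substitution and indel errors to a read
#'
#' Each base independently suffers a substitution with probability
#' `substitution_rate`; independently, at each position an indel event
#' occurs with probability `indel_rate` (insertion of a random base before
#' the position, or deletion of the position, with equal odds). With a
#' `seed` in the model the result is deterministic; otherwise the caller's
#' RNG state is used.
#'
#' @param read read string
#' @param model an [errorModel()]
#' @return mutated read string
#' @export
applyErrors <- function(read, model = errorModel()) {
  stopifnot(inherits(model, "trb_error_model"))
  if (model$substitution_rate == 0 && model$indel_rate == 0) return(read)
  .withSeed(model$seed, {
    chars <- strsplit(read, "")[[1L]]
    n <- length(chars)
    sub <- which(runif(n) < model$substitution_rate)
    if (length(sub)) {
      chars[sub] <- vapply(chars[sub], function(b) {
        sample(setdiff(.BASES, b), 1L)
      }, character(1), USE.NAMES = FALSE)
    }
    ind <- which(runif(n) < model$indel_rate)
    if (length(ind)) {
      isIns <- runif(length(ind)) < 0.5
      del <- ind[!isIns]
      ins <- ind[isIns]
      pieces <- chars
      if (length(del)) pieces[del] <- ""
      if (length(ins)) {
        pieces[ins] <- paste0(sample(.BASES, length(ins), replace = TRUE),
                              pieces[ins])
      }
      chars <- pieces
    }
    paste(chars, collapse = "")
  })
}

.checkBarcodes <- function(barcodes) {
  if (any(nchar(barcodes) != 10L)) stop("barcodes must be 10 bp")
  if (anyDuplicated(barcodes)) stop("duplicate barcode in sample sheet")
  if (length(barcodes) > 1L) {
    for (i in seq_len(length(barcodes) - 1L)) {
      for (j in (i + 1L):length(barcodes)) {
        if (.hamming(barcodes[i], barcodes[j]) < 3L) {
          stop("barcodes must have pairwise Hamming distance >= 3")
        }
      }
    }
  }
  invisible(barcodes)
}

#' Generate sample barcodes with pairwise Hamming distance >= 3
#'
#' @param n number of barcodes
#' @return character vector of 10-mers (uses the caller's RNG state)
#' @export
makeBarcodes <- function(n) {
  out <- character(0)
  while (length(out) < n) {
    cand <- .randDNA(10L)
    if (all(vapply(out, function(b) .hamming(b, cand) >= 3L, logical(1)))) {
      out <- c(out, cand)
    }
  }
  out
}

.checkMix <- function(mix) {
  if (is.null(names(mix)) || !all(names(mix) %in% TRB_CATEGORIES)) {
    stop("mix must be named by categories ", paste(TRB_CATEGORIES, collapse = "/"))
  }
  if (any(mix < 0)) stop("mix fractions must be non-negative")
  if (abs(sum(mix) - 1) > 1e-9) stop("mix fractions must sum to 1")
  invisible(mix)
}

#' Simulate a pooled multi-sample cohort
#'
#' Draws per-read categories from `mix`, constructs inserts with
#' [simulateInsert()], attaches technical sequences with the sample barcode,
#' applies the error model, and pools reads across samples. A clonal CR
#' spike (fixed V/J/CDR3 at a set fraction of all reads) can be planted to
#' emulate a neoplastic clone.
#'
#' @param locus a [TcrbLocus-class]
#' @param samples data.frame with columns `sample_id`, `barcode` (10-mers,
#'   pairwise Hamming distance >= 3), `n_reads`
#' @param mix named category fractions (single vector recycled to all
#'   samples, or a list keyed by sample_id)
#' @param spike `NULL`, or list(`v`, `j`, `cdr3`, `fraction`) with
#'   `fraction` (of all reads in a sample) at most the CR fraction; applied
#'   to every sample (or a list keyed by sample_id)
#' @param model an [errorModel()]
#' @param seed integer seed; the full cohort is reproducible from it
#' @param asRandomDonorProb passed to [simulateInsert()]
#' @return list with `reads` ([Biostrings::DNAStringSet], names =
#'   read ids), `truth` (data.frame: read_id, sample_id, category, subtype,
#'   v_name, d_name, j_name, c_name, cdr3_seq, spike), and `barcodes`
#'   (data.frame sample_id, barcode)
#' @export
simulateCohort <- function(locus, samples, mix = defaultCategoryMix(),
                           spike = NULL, model = errorModel(), seed = 1L,
                           asRandomDonorProb = 0) {
  stopifnot(is.data.frame(samples),
            all(c("sample_id", "barcode", "n_reads") %in% names(samples)))
  .checkBarcodes(samples$barcode)
  getMix <- function(sid) {
    m <- if (is.list(mix)) mix[[sid]] else mix
    .checkMix(m)
  }
  getSpike <- function(sid) {
    if (is.null(spike)) return(NULL)
    if (!is.null(names(spike)) && all(c("v", "j", "cdr3", "fraction") %in%
                                      names(spike))) spike else spike[[sid]]
  }
  info <- .simInfo(locus)

  .withSeed(seed, {
    nTotal <- sum(samples$n_reads)
    reads <- character(nTotal)
    tr_id <- character(nTotal); tr_sid <- character(nTotal)
    tr_cat <- character(nTotal); tr_sub <- character(nTotal)
    tr_v <- character(nTotal); tr_d <- character(nTotal)
    tr_j <- character(nTotal); tr_c <- character(nTotal)
    tr_cdr3 <- character(nTotal); tr_don <- logical(nTotal)
    tr_spike <- logical(nTotal)
    pos <- 0L
    for (si in seq_len(nrow(samples))) {
      sid <- samples$sample_id[si]
      bc <- samples$barcode[si]
      n <- samples$n_reads[si]
      m <- getMix(sid)
      sp <- getSpike(sid)
      if (!is.null(sp) && sp$fraction > m[["CR"]] + 1e-9) {
        stop("clonal spike fraction exceeds the CR fraction")
      }
      cats <- sample(names(m), n, replace = TRUE, prob = m)
      for (ri in seq_len(n)) {
        rid <- sprintf("%s_r%05d", sid, ri)
        isSpike <- FALSE
        if (cats[ri] == "CR" && !is.null(sp) &&
            runif(1) < sp$fraction / m[["CR"]]) {
          isSpike <- TRUE
          j <- info$js[info$js$name == sp$j, ]
          v <- info$vs[info$vs$name == sp$v, ]
          cc <- .clusterC(info, sp$j)
          vTake <- sample(80:(v$end - v$start + 1L), 1L)
          ins <- list(
            seq = paste0(.ref(info, v$end - vTake + 1L, v$end), sp$cdr3,
                         .ref(info, j$start, j$end),
                         .ref(info, cc$start, cc$start + info$cTake - 1L)),
            truth = list(category = "CR", subtype = "V-(D)-J-(C)",
                         v_name = sp$v, d_name = NA_character_,
                         j_name = sp$j, c_name = cc$name,
                         cdr3_seq = sp$cdr3, donor_planted = NA))
        } else {
          ins <- simulateInsert(locus, cats[ri], info = info,
                                asRandomDonorProb = asRandomDonorProb)
        }
        raw <- attachTechnical(ins$seq, bc)
        mutated <- applyErrors(raw$read, model)
        pos <- pos + 1L
        reads[pos] <- mutated
        tr <- ins$truth
        tr_id[pos] <- rid; tr_sid[pos] <- sid
        tr_cat[pos] <- tr$category; tr_sub[pos] <- tr$subtype
        tr_v[pos] <- tr$v_name; tr_d[pos] <- tr$d_name
        tr_j[pos] <- tr$j_name; tr_c[pos] <- tr$c_name
        tr_cdr3[pos] <- tr$cdr3_seq; tr_don[pos] <- tr$donor_planted
        tr_spike[pos] <- isSpike
      }
    }
    truth <- data.frame(read_id = tr_id, sample_id = tr_sid,
                        category = tr_cat, subtype = tr_sub,
                        v_name = tr_v, d_name = tr_d, j_name = tr_j,
                        c_name = tr_c, cdr3_seq = tr_cdr3,
                        donor_planted = tr_don, spike = tr_spike,
                        stringsAsFactors = FALSE)
    ## shuffle pool order (samples were generated block-wise)
    ord <- sample.int(nTotal)
    pooled <- DNAStringSet(stats::setNames(reads[ord], tr_id[ord]))
    list(reads = pooled, truth = truth,
         barcodes = samples[, c("sample_id", "barcode")])
  })
}

#' Write a simulated cohort to disk
#'
#' Writes `<prefix>.fasta` (or `.fastq` with constant Q30), a truth table
#' `<prefix>_truth.tsv` and a barcode map `<prefix>_barcodes.tsv`.
#'
#' @param cohort result of [simulateCohort()]
#' @param prefix output path prefix
#' @param format `"fasta"` or `"fastq"`
#' @return the prefix, invisibly
#' @export
writeCohort <- function(cohort, prefix, format = c("fasta", "fastq")) {
  format <- match.arg(format)
  if (format == "fasta") {
    Biostrings::writeXStringSet(cohort$reads, paste0(prefix, ".fasta"))
  } else {
    q <- Biostrings::PhredQuality(
      vapply(width(cohort$reads), function(w) strrep("?", w), character(1)))
    x <- Biostrings::QualityScaledDNAStringSet(cohort$reads, q)
    Biostrings::writeQualityScaledXStringSet(x, paste0(prefix, ".fastq"))
  }
  utils::write.table(cohort$truth, paste0(prefix, "_truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$barcodes, paste0(prefix, "_barcodes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(prefix)
}
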