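## Per-sample repertoire summaries: category compositions, VJ/CDR3
## clonotype tables with top-k dominance, J usage and the NR J2-2P~J2-3
## split.

.fracTable <- function(df, keyCol) {
  out <- lapply(split(df, df$sample_id), function(d) {
    t <- table(d[[keyCol]])
    data.frame(sample_id = d$sample_id[1L], key = names(t),
               count = as.integer(t), fraction = as.numeric(t) / sum(t),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Per-sample composition over the six repertoire categories
#'
#' Fractions of CR, PR, NR, NS, AS and AR reads per sample, computed after
#' excluding UC and CH reads (which are uncertain/artefactual and excluded
#' from repertoire statistics). The full eight-way table is attached as
#' attribute `"eightway"` for audit.
#'
#' @param labels result of [classifyReads()]
#' @return data.frame `sample_id`, `key` (category), `count`, `fraction`;
#'   fractions per sample sum to 1 over the six categories
#' @export
categoryComposition <- function(labels) {
  eight <- .fracTable(labels, "category")
  keep <- labels[!labels$category %in% c("UC", "CH"), , drop = FALSE]
  if (nrow(keep) == 0L) {
    warning("no reads left after excluding UC/CH")
    out <- data.frame(sample_id = character(), key = character(),
                      count = integer(), fraction = numeric(),
                      stringsAsFactors = FALSE)
  } else {
    out <- .fracTable(keep, "category")
  }
  attr(out, "eightway") <- eight
  out
}

#' VJ-pairing and CDR3 clonotype tables with top-k dominance
#'
#' Restricted to statistics-eligible CR reads (V-(D)-only CR reads are
#' excluded). The CDR3 of a read is the nucleotide subsequence between the
#' end of its V alignment and the start of its J alignment; clonotypes are
#' keyed by (V name, J name, CDR3 sequence).
#'
#' @param labels result of [classifyReads()]
#' @param processed the processed-read table (`read_id`, `sequence`) used
#'   to extract CDR3 nucleotides
#' @return list with `vj` (per-sample VJ counts/fractions), `cdr3`
#'   (per-sample clonotype records) and `topk` (per-sample fraction of the
#'   k-th most abundant VJ pairing and CDR3 clonotype, k = 1..10)
#' @export
clonotypeTables <- function(labels, processed) {
  cr <- labels[labels$category == "CR" & labels$stats_eligible &
                 !is.na(labels$j_name), , drop = FALSE]
  emptyTab <- data.frame(sample_id = character(), key = character(),
                         count = integer(), fraction = numeric())
  if (nrow(cr) == 0L) {
    return(list(vj = emptyTab, cdr3 = emptyTab,
                topk = data.frame(sample_id = character(), table = character(),
                                  k = integer(), fraction = numeric())))
  }
  seqs <- stats::setNames(processed$sequence, processed$read_id)
  cdr3 <- substr(seqs[cr$read_id], cr$v_read_end + 1L, cr$j_read_start - 1L)
  cr$vj_key <- paste(cr$v_name, cr$j_name, sep = "|")
  cr$cdr3_key <- paste(cr$v_name, cr$j_name, unname(cdr3), sep = "|")
  cr$cdr3_seq <- unname(cdr3)

  vj <- .fracTable(cr, "vj_key")
  cd <- .fracTable(cr, "cdr3_key")
  cd$cdr3_seq <- vapply(strsplit(cd$key, "|", fixed = TRUE), `[`, character(1), 3L)

  topk <- do.call(rbind, lapply(split(cr, cr$sample_id), function(d) {
    mk <- function(keys, lab) {
      f <- sort(table(keys), decreasing = TRUE) / length(keys)
      k <- seq_len(min(10L, length(f)))
      data.frame(sample_id = d$sample_id[1L], table = lab, k = k,
                 fraction = as.numeric(f[k]), stringsAsFactors = FALSE)
    }
    rbind(mk(d$vj_key, "vj"), mk(d$cdr3_key, "cdr3"))
  }))
  rownames(topk) <- NULL
  list(vj = vj, cdr3 = cd, topk = topk)
}

#' J-gene usage within a category
#'
#' Per-sample fraction of each J gene among the reads of one category
#' (CR, PR or NR).
#'
#' @param labels result of [classifyReads()]
#' @param category one of `"CR"`, `"PR"`, `"NR"`
#' @return data.frame `sample_id`, `key` (J gene), `count`, `fraction`;
#'   zero rows for samples without reads of the category
#' @export
jUsage <- function(labels, category = c("NR", "CR", "PR")) {
  category <- match.arg(category)
  d <- labels[labels$category == category & !is.na(labels$j_name), ,
              drop = FALSE]
  if (category == "CR") d <- d[d$stats_eligible, , drop = FALSE]
  if (nrow(d) == 0L) {
    return(data.frame(sample_id = character(), key = character(),
                      count = integer(), fraction = numeric()))
  }
  .fracTable(d, "j_name")
}

#' Split NR reads into J2-2P~J2-3, J2-3-only and other-J
#'
#' An NR read on J2-3 is `J2-2P~J2-3` iff its J alignment (including the
#' upstream-intron extension) covers at least `minOverlap` bp of the
#' annotated J2-2P pseudogene interval; otherwise `J2-3_only`. NR reads on
#' other J genes are binned `other-J`. The two J2-3 bins partition the
#' J2-3 NR reads.
#'
#' @param labels result of [classifyReads()]
#' @param locus a [TcrbLocus-class]
#' @param minOverlap minimum J2-2P overlap in bp (default 1)
#' @return data.frame `sample_id`, `key` (bin), `count`, `fraction`
#' @export
nrSubtypeSplit <- function(labels, locus, minOverlap = 1L) {
  nr <- labels[labels$category == "NR" & !is.na(labels$j_name), , drop = FALSE]
  if (nrow(nr) == 0L) {
    return(data.frame(sample_id = character(), key = character(),
                      count = integer(), fraction = numeric()))
  }
  tab <- .segTable(locus)
  ps <- tab[tab$kind == "pseudo-J", ][1L, ]
  ov <- pmin(nr$j_ref_end, ps$end) - pmax(nr$j_ref_start, ps$start) + 1L
  nr$bin <- ifelse(nr$j_name != "J2-3", "other-J",
                   ifelse(ov >= minOverlap, "J2-2P~J2-3", "J2-3_only"))
  .fracTable(nr, "bin")
}
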