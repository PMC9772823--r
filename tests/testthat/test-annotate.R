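test_that("mergeBroken applies the relative-gap rule with the 0/0 convention", {
  base <- function(dr, dg) {
    rbind(mkSeg(1L, 50L, 101L, 150L),
          mkSeg(50L + dr + 1L, 50L + dr + 60L, 150L + dg + 1L, 150L + dg + 60L))
  }
  expect_equal(nrow(mergeBroken(base(10L, 12L))), 1L)  # |diff| = 2 < 6
  expect_equal(nrow(mergeBroken(base(5L, 20L))), 2L)   # 15 >= 10
  expect_equal(nrow(mergeBroken(base(0L, 0L))), 1L)    # abutting: merged
  ## gaps beyond the close threshold are never touched
  expect_equal(nrow(mergeBroken(base(2L, 100L))), 2L)
  m <- mergeBroken(base(10L, 12L))
  expect_equal(m$read_start, 1L)
  expect_equal(m$read_end, 120L)
})

test_that("mergeBroken is idempotent and never loses aligned length", {
  set.seed(61)
  for (rep in 1:50) {
    segs <- randomSegs(sample(2:4, 1))
    m1 <- mergeBroken(segs)
    m2 <- mergeBroken(m1)
    expect_identical(m1, m2)
    alen <- function(d) sum(d$read_end - d$read_start + 1L)
    expect_gte(alen(m1), alen(segs))
  }
})

test_that("fixCOrder relabels out-of-order C1 as C2, one direction only", {
  locus <- tLocus()
  tab <- tSegTable()
  c1 <- tab[tab$name == "C1", ]; c2 <- tab[tab$name == "C2", ]
  j23 <- tab[tab$name == "J2-3", ]
  v1 <- tab[tab$name == "V1", ]
  j11 <- tab[tab$name == "J1-1", ]

  ## V - J2-3 - C1: C1 lies upstream of J2-3 in the reference
  segs <- rbind(
    mkSeg(1L, 100L, v1$end - 99L, v1$end, name = "V1", kind = "V"),
    mkSeg(101L, 150L, j23$start, j23$end, name = "J2-3", kind = "J"),
    mkSeg(151L, 250L, c1$start, c1$start + 99L, name = "C1", kind = "C"))
  fixed <- fixCOrder(segs, locus)
  expect_identical(fixed$name[3], "C2")
  expect_equal(fixed$ref_start[3], c2$start)
  ## ordered V - J1-1 - C1 is untouched
  ok <- rbind(
    mkSeg(1L, 100L, v1$end - 99L, v1$end, name = "V1", kind = "V"),
    mkSeg(101L, 150L, j11$start, j11$end, name = "J1-1", kind = "J"),
    mkSeg(151L, 250L, c1$start, c1$start + 99L, name = "C1", kind = "C"))
  expect_identical(fixCOrder(ok, locus)$name, c("V1", "J1-1", "C1"))
  ## a lone C1 has no order violation
  lone <- mkSeg(1L, 100L, c1$start, c1$start + 99L, name = "C1", kind = "C")
  expect_identical(fixCOrder(lone, locus)$name, "C1")
  ## C2 is never relabelled to C1 even when out of order
  c2bad <- rbind(
    mkSeg(1L, 100L, c2$start, c2$start + 99L, name = "C2", kind = "C"),
    mkSeg(101L, 150L, j23$start, j23$end, name = "J2-3", kind = "J"))
  expect_identical(fixCOrder(c2bad, locus)$name, c("C2", "J2-3"))
})

test_that("read overlaps split at GT/AG-consistent breakpoints", {
  locus <- tLocus()
  tab <- tSegTable()
  j23 <- tab[tab$name == "J2-3", ]
  c2 <- tab[tab$name == "C2", ]
  ## upstream alignment overshoots 6 bp past the J donor; downstream starts
  ## 6 bp before the C acceptor: unique consistent breakpoint at J end
  segs <- rbind(
    mkSeg(1L, 56L, j23$start, j23$start + 55L),
    mkSeg(45L, 110L, c2$start - 6L, c2$start + 59L))
  out <- splitOverlapAtSplice(segs, locus)
  expect_equal(out$read_end[1], 50L)
  expect_equal(out$ref_end[1], j23$end)
  expect_equal(out$read_start[2], 51L)
  expect_equal(out$ref_start[2], c2$start)
  expect_false(any(grepl("no_splice_support", out$flags)))

  ## no GT/AG candidate: midpoint fallback with flag; the upstream ref
  ## window is chosen free of GT dinucleotides so no candidate can pass
  s <- as.character(locusSequence(locus))
  hasGT <- function(from, to) {
    any(substring(s, from:to, from:to + 1L) == "GT")
  }
  aEnd0 <- 1000L
  while (hasGT(aEnd0 + 1L - 10L, aEnd0 + 2L)) aEnd0 <- aEnd0 + 1L
  mid <- rbind(mkSeg(1L, 60L, aEnd0 - 59L, aEnd0),
               mkSeg(51L, 120L, 2000L, 2069L))
  outMid <- splitOverlapAtSplice(mid, locus)
  expect_true(all(grepl("no_splice_support", outMid$flags)))
  expect_equal(outMid$read_end[1] + 1L, outMid$read_start[2])
  ## zero overlap: unchanged coordinates
  apart <- rbind(mkSeg(1L, 50L, 1000L, 1049L),
                 mkSeg(60L, 120L, 2000L, 2060L))
  outApart <- splitOverlapAtSplice(apart, locus)
  expect_equal(outApart$read_start, apart$read_start)
  expect_equal(outApart$read_end, apart$read_end)
})

test_that("chain selection matches exhaustive subset enumeration", {
  set.seed(71)
  for (rep in 1:300) {
    segs <- randomSegs(sample(2:4, 1))
    got <- buildChain(segs)
    want <- oracleChain(got[, setdiff(names(got), "selected")])
    expect_identical(which(got$selected), want$idx)
    expect_identical(attr(got, "chain_strand"), want$strand)
    expect_equal(attr(got, "chain_score"), want$score)
  }
  expect_error(buildChain(mkSeg(1L, 2L, 3L, 4L)[0, ]), "empty")
})

test_that("cross-strand conflicts are retained as evidence", {
  segs <- rbind(mkSeg(1L, 100L, 500L, 599L, strand = "+"),
                mkSeg(120L, 160L, 3000L, 3040L, strand = "-"))
  out <- buildChain(segs)
  expect_equal(sum(out$selected), 1L)
  expect_equal(nrow(out), 2L)  # conflicting segment kept
  expect_identical(attr(out, "chain_strand"), "+")
})

test_that("error-free reads annotate to their true structure", {
  locus <- tLocus()
  set.seed(81)
  ## NR: [intron >= 15][J][C] as two segments
  ins <- simulateInsert(locus, "NR")
  ann <- annotateReads(stats::setNames(ins$seq, "r"), locus)
  segs <- ann$segments[ann$segments$selected, ]
  expect_identical(segs$kind, c("J", "C"))
  expect_gte(segs$upstream_intron_bp[1], 15L)
  expect_identical(segs$name[1], ins$truth$j_name)
  ## minus-strand read: same classification after sense reversal
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(ins$seq)))
  annRc <- annotateReads(stats::setNames(rc, "r"), locus)
  expect_identical(annRc$chains$chain_strand, "-")
  expect_identical(annRc$chains$kinds, "JC")
  expect_identical(classifyReads(annRc)$category, "NR")
  ## random non-locus sequence is unannotatable
  junk <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE),
                collapse = "")
  annJunk <- annotateReads(stats::setNames(junk, "r"), locus)
  expect_false(annJunk$chains$annotated)
  ## V/J names recovered exactly on error-free CR reads
  for (i in 1:20) {
    cr <- simulateInsert(locus, "CR")
    a <- annotateReads(stats::setNames(cr$seq, "r"), locus)
    expect_identical(a$chains$v_name, cr$truth$v_name)
    expect_identical(a$chains$j_name, cr$truth$j_name)
  }
})
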