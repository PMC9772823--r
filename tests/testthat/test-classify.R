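## shorthand: classify an abstract chain summary
cz <- function(kinds, intron = 0L, head = 0L, tail = 0L, rss = NA_integer_,
               nC = sum(kinds == "C"), strandOK = TRUE, orderOK = TRUE,
               th = defaultThresholds()) {
  categorizeEvidence(kinds, nC, strandOK, orderOK, intron, head, tail, rss, th)
}

test_that("category rules and boundary semantics are exact", {
  ## completely recombined
  expect_identical(cz(c("V", "D", "J", "C"))$category, "CR")
  expect_identical(cz(c("V", "J"))$category, "CR")
  vd <- cz(c("V", "D"), tail = 60L)
  expect_identical(vd$category, "CR")
  expect_identical(vd$subtype, "V-(D)-only")
  expect_false(vd$stats_eligible)
  expect_identical(cz(c("V", "D"), tail = 61L)$category, "UC")
  expect_identical(cz("V", tail = 0L)$category, "CR")  # read ends within V
  ## partially recombined
  expect_identical(cz(c("D", "J", "C"), intron = 15L)$category, "PR")
  expect_identical(cz(c("D", "J", "C"), intron = 14L)$category, "UC")
  dOnly <- cz("D", tail = 30L)
  expect_identical(dOnly$category, "PR")
  expect_false(dOnly$stats_eligible)
  ## non-recombined boundary at 15 bp intron
  expect_identical(cz(c("J", "C"), intron = 15L)$category, "NR")
  expect_identical(cz(c("J", "C"), intron = 16L)$category, "NR")
  expect_identical(cz(c("J", "C"), intron = 14L)$category, "UC")
  ## aberrant recombination within 30 bp of the cryptic RSS, else AS
  expect_identical(cz(c("I", "J", "C"), rss = 10L)$category, "AR")
  expect_identical(cz(c("I", "J", "C"), rss = 30L)$category, "AR")
  expect_identical(cz(c("I", "J", "C"), rss = 31L)$category, "AS")
  expect_identical(cz(c("I", "J", "C"), rss = 50L)$category, "AS")
  expect_identical(cz(c("I", "J"), rss = NA_integer_)$category, "AS")
  ## aberrant splicing configurations
  expect_identical(cz(c("V", "C"))$category, "AS")
  expect_identical(cz(c("D", "C"))$category, "AS")
  expect_identical(cz(c("I", "C"))$category, "AS")
  ## non-spliced with the 120 bp unaligned boundary
  expect_identical(cz("C", intron = 20L, tail = 120L)$category, "NS")
  expect_identical(cz("C", intron = 20L, tail = 121L)$category, "UC")
  expect_identical(cz("C", intron = 14L)$category, "UC")
  ## chimeric configurations dominate everything
  expect_identical(cz(c("C", "J", "C"))$category, "CH")
  expect_identical(cz(c("V", "J", "C"), strandOK = FALSE)$category, "CH")
  expect_identical(cz(c("V", "J", "C"), orderOK = FALSE)$category, "CH")
})

test_that("classifier agrees with the independent predicate oracle on random templates", {
  templates <- allKindTemplates(4L)
  set.seed(91)
  pick <- sample(length(templates), 400)
  for (i in pick) {
    kinds <- templates[[i]]
    intron <- sample(c(0L, 14L, 15L, 16L, 40L), 1)
    tail <- sample(c(0L, 59L, 61L, 120L, 121L), 1)
    rss <- sample(c(NA_integer_, 29L, 31L), 1)
    got <- cz(kinds, intron = intron, tail = tail, rss = rss)$category
    want <- oracleCategory(kinds, sum(kinds == "C"), TRUE, TRUE,
                           intron, 0L, tail, rss)
    expect_identical(got, want)
  }
})

test_that("classifyChain reports category with machine-checkable evidence", {
  locus <- tLocus()
  set.seed(92)
  ins <- simulateInsert(locus, "AR")
  ann <- annotateReads(stats::setNames(ins$seq, "r"), locus)
  segs <- ann$segments
  out <- classifyChain(segs, locus, readLen = nchar(ins$seq))
  expect_identical(out$category, "AR")
  expect_lte(out$evidence$rss_distance, 30L)
  expect_identical(out$evidence$kinds, c("I", "J", "C"))
  expect_error(classifyChain(segs[0, ], locus, 100L), "empty")
})

test_that("every read receives exactly one category and counts are conserved", {
  pl <- tPipeline()
  lab <- pl$lab
  expect_true(all(lab$category %in% TRB_CATEGORIES))
  expect_equal(nrow(lab), sum(pl$ann$chains$annotated))
  expect_equal(sum(table(lab$category)), nrow(lab))
})

test_that("splice evidence summary recovers the planted donor 174 bp upstream of D1", {
  locus <- tLocus()
  set.seed(93)
  bc <- makeBarcodes(1)
  samples <- data.frame(sample_id = "S", barcode = bc, n_reads = 300)
  coh <- simulateCohort(locus, samples, mix = c(AS = 1), seed = 303)
  pp <- preprocessReads(coh$reads, coh$barcodes)
  ann <- annotateReads(pp$processed, locus)
  lab <- classifyReads(ann)
  sm <- spliceEvidenceSummary(ann, lab, locus)
  ic <- sm[sm$subtype == "I-C", ]
  expect_equal(ic$modal_donor_offset_d1, -174L)
  expect_equal(ic$donor_gt_frac, 1)
  vc <- sm[sm$subtype == "V-C", ]
  expect_equal(vc$donor_gt_frac, 1)
  expect_equal(vc$acceptor_ag_frac, 1)

  ## no AS reads: empty summary
  labNo <- lab[lab$category != "AS", , drop = FALSE]
  expect_equal(nrow(spliceEvidenceSummary(ann, labNo, locus)), 0L)

  ## randomised donors: GT support matches the planted fraction
  cohR <- simulateCohort(locus, samples, mix = c(AS = 1), seed = 304,
                         asRandomDonorProb = 0.4)
  ppR <- preprocessReads(cohR$reads, cohR$barcodes)
  annR <- annotateReads(ppR$processed, locus)
  labR <- classifyReads(annR)
  smR <- spliceEvidenceSummary(annR, labR, locus)
  icR <- smR[smR$subtype == "I-C", ]
  truthIC <- merge(labR[labR$category == "AS", c("read_id", "subtype")],
                   cohR$truth[, c("read_id", "donor_planted", "subtype")],
                   by = "read_id")
  truthFrac <- mean(truthIC$donor_planted[truthIC$subtype.y == "I-C"])
  expect_lt(abs(icR$donor_gt_frac - truthFrac),
            3 * sqrt(0.25 / icR$n) + 0.02)
})
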