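## minimal label rows for composition tests
mkLabels <- function(categories, sample_id = "S") {
  data.frame(read_id = sprintf("r%04d", seq_along(categories)),
             sample_id = sample_id, category = categories,
             subtype = NA_character_, stats_eligible = TRUE,
             j_name = NA_character_, stringsAsFactors = FALSE)
}

test_that("category composition excludes UC/CH and normalises to one", {
  lab <- mkLabels(c(rep("CR", 41), rep("NR", 59)))
  cc <- categoryComposition(lab)
  expect_equal(cc$fraction[cc$key == "CR"], 0.41)
  expect_equal(cc$fraction[cc$key == "NR"], 0.59)
  expect_equal(sum(cc$fraction), 1)

  ## UC/CH are excluded from the six-way fractions but kept in the audit
  lab2 <- mkLabels(c(rep("CR", 50), rep("NR", 30), rep("UC", 15),
                     rep("CH", 5)))
  cc2 <- categoryComposition(lab2)
  expect_equal(cc2$fraction[cc2$key == "CR"], 50 / 80)
  eight <- attr(cc2, "eightway")
  expect_equal(eight$count[eight$key == "UC"], 15L)
  expect_equal(sum(cc2$fraction), 1)

  expect_warning(ccU <- categoryComposition(mkLabels(rep("UC", 5))),
                 "no reads")
  expect_equal(nrow(ccU), 0L)
})

test_that("pipeline compositions recover the simulated mix", {
  pl <- tPipeline()
  cc <- categoryComposition(pl$lab)
  mix <- defaultCategoryMix()
  sixMix <- mix[setdiff(names(mix), c("UC", "CH"))]
  sixMix <- sixMix / sum(sixMix)
  for (sid in unique(cc$sample_id)) {
    d <- cc[cc$sample_id == sid, ]
    expect_equal(sum(d$fraction), 1, tolerance = 1e-9)
    n <- sum(d$count)
    for (k in names(sixMix)) {
      f <- d$fraction[d$key == k]
      if (length(f) == 0) f <- 0
      expect_lt(abs(f - sixMix[[k]]),
                4 * sqrt(sixMix[[k]] * (1 - sixMix[[k]]) / n) + 0.01)
    }
  }
})

test_that("clonotype tables count eligible CR reads and rank dominance", {
  pl <- tPipeline()
  ct <- clonotypeTables(pl$lab, pl$pp$processed)
  ## fractions normalise per sample; top-k fractions are non-increasing
  for (sid in unique(ct$vj$sample_id)) {
    expect_equal(sum(ct$vj$fraction[ct$vj$sample_id == sid]), 1,
                 tolerance = 1e-9)
    expect_equal(sum(ct$cdr3$fraction[ct$cdr3$sample_id == sid]), 1,
                 tolerance = 1e-9)
    for (tb in c("vj", "cdr3")) {
      f <- ct$topk$fraction[ct$topk$sample_id == sid & ct$topk$table == tb]
      expect_true(all(diff(f) <= 1e-12))
    }
  }
  ## V/J assignments agree with the simulated truth for eligible CR reads
  truth <- pl$cohort$truth
  eligible <- pl$lab[pl$lab$category == "CR" & pl$lab$stats_eligible, ]
  m <- merge(eligible[, c("read_id", "v_name", "j_name")],
             truth[, c("read_id", "v_name", "j_name", "cdr3_seq")],
             by = "read_id")
  expect_true(all(m$v_name.x == m$v_name.y))
  expect_true(all(m$j_name.x == m$j_name.y))

  ## ineligible CR reads contribute to no table
  lab1 <- pl$lab[pl$lab$category == "CR", ][1, , drop = FALSE]
  lab1$stats_eligible <- FALSE
  empty <- clonotypeTables(lab1, pl$pp$processed)
  expect_equal(nrow(empty$vj), 0L)
  ## a single CR read gives top-1 fraction 1
  lab2 <- pl$lab[pl$lab$category == "CR" & pl$lab$stats_eligible, ][1, ,
                                                                   drop = FALSE]
  one <- clonotypeTables(lab2, pl$pp$processed)
  expect_equal(one$topk$fraction[one$topk$k == 1], c(1, 1))
})

test_that("J usage is a per-sample distribution over J genes", {
  pl <- tPipeline()
  for (cat0 in c("NR", "CR", "PR")) {
    ju <- jUsage(pl$lab, cat0)
    for (sid in unique(ju$sample_id)) {
      expect_equal(sum(ju$fraction[ju$sample_id == sid]), 1, tolerance = 1e-9)
    }
    ## J assignments match simulated truth
    d <- pl$lab[pl$lab$category == cat0 & !is.na(pl$lab$j_name), ]
    m <- merge(d[, c("read_id", "j_name")],
               pl$cohort$truth[, c("read_id", "j_name")], by = "read_id")
    expect_true(all(m$j_name.x == m$j_name.y))
  }
  ## NR usage is skewed to J2-3, CR usage is not
  juNR <- jUsage(pl$lab, "NR")
  fNR <- sum(juNR$count[juNR$key == "J2-3"]) / sum(juNR$count)
  juCR <- jUsage(pl$lab, "CR")
  fCR <- sum(juCR$count[juCR$key == "J2-3"]) / sum(juCR$count)
  expect_gt(fNR, 0.5)
  expect_lt(fCR, 0.5)
  expect_equal(nrow(jUsage(pl$lab[0, ], "NR")), 0L)
})

test_that("NR J2-3 reads split by J2-2P coverage into a clean partition", {
  pl <- tPipeline()
  sp <- nrSubtypeSplit(pl$lab, tLocus())
  nr <- pl$lab[pl$lab$category == "NR", ]
  ## partition: the three bins cover all NR reads
  expect_equal(sum(sp$count), nrow(nr))
  byBin <- tapply(sp$count, sp$key, sum)
  expect_equal(sum(byBin[c("J2-2P~J2-3", "J2-3_only")], na.rm = TRUE),
               sum(nr$j_name == "J2-3"))
  ## bins agree with simulated truth subtypes
  truth <- pl$cohort$truth
  m <- merge(nr[, c("read_id", "j_name", "j_ref_start")],
             truth[truth$category == "NR", c("read_id", "subtype")],
             by = "read_id")
  tab <- tSegTable()
  ps <- tab[tab$kind == "pseudo-J", ]
  called <- ifelse(m$j_name != "J2-3", "other-J",
                   ifelse(m$j_ref_start <= ps$end, "J2-2P~J2-3", "J2-3_only"))
  expect_true(all(called == m$subtype))
})
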