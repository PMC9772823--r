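## primers taken from the locus itself: the planted 20-mer V suffixes and
## the constant-region primer (which binds C on the minus strand)
tPrimers <- function() {
  tab <- tSegTable()
  s <- as.character(locusSequence(tLocus()))
  vs <- tab[tab$kind == "V", ]
  data.frame(
    primer_id = c(paste0("P", vs$name), "PC"),
    seq = c(substring(s, vs$end - 19L, vs$end),
            "GGGTGGGAACACCTTGTTCAGGT"),
    stringsAsFactors = FALSE)
}

test_that("primer mapping finds planted sites and respects the mismatch cap", {
  locus <- tLocus()
  tab <- tSegTable()
  pm <- mapPrimers(tPrimers(), locus, kinds = c("V", "C"))
  vs <- tab$name[tab$kind == "V"]
  for (v in vs) {
    h <- pm$hits[pm$hits$segment_name == v, ]
    expect_equal(nrow(h), 1L)
    expect_identical(h$primer_id, paste0("P", v))
    expect_equal(h$mismatches, 0L)
    expect_equal(h$ref_end, tab$end[tab$name == v])
    expect_identical(h$strand, "+")
  }
  ## the C primer binds the minus strand: perfect at C1, one mismatch at C2
  hC1 <- pm$hits[pm$hits$segment_name == "C1", ]
  hC2 <- pm$hits[pm$hits$segment_name == "C2", ]
  expect_identical(hC1$strand, "-")
  expect_equal(hC1$mismatches, 0L)
  expect_equal(hC2$mismatches, 1L)

  ## a primer with > 4 mismatches everywhere leaves segments unmapped
  set.seed(14)
  junk <- data.frame(primer_id = "PX",
                     seq = paste(sample(c("A", "C", "G", "T"), 25,
                                        replace = TRUE), collapse = ""))
  pmX <- mapPrimers(junk, locus, kinds = "J")
  expect_equal(nrow(pmX$hits), 0L)
  expect_setequal(pmX$unmapped, tab$name[tab$kind == "J"])
  expect_error(mapPrimers(data.frame(primer_id = "S", seq = "ACGT"), locus),
               "15-30")
})

test_that("per-segment best hit agrees with an all-window brute force", {
  locus <- tLocus()
  s <- as.character(locusSequence(locus))
  tab <- tSegTable()
  primers <- tPrimers()[c(1, 6), ]
  pm <- mapPrimers(primers, locus, maxMismatch = 6L, kinds = c("V", "C"))
  for (i in seq_len(nrow(primers))) {
    bf <- brutePrimerHits(primers$seq[i], s, maxMismatch = 6L)
    for (k in seq_len(nrow(tab))) {
      ov <- bf[bf$ref_start <= tab$end[k] & bf$ref_end >= tab$start[k], ,
               drop = FALSE]
      if (nrow(ov) == 0L) next
      ov <- ov[order(ov$mismatches, ov$ref_start), ]
      h <- pm$hits[pm$hits$segment_name == tab$name[k] &
                     pm$hits$primer_id == primers$primer_id[i], ]
      if (nrow(h) == 1L) {
        ## the retained hit is never worse than the brute-force best
        expect_lte(h$mismatches, ov$mismatches[1])
      }
    }
  }
})

test_that("variant assessment reports site membership, 3' distance and match delta", {
  locus <- tLocus()
  s <- as.character(locusSequence(locus))
  pm <- mapPrimers(tPrimers(), locus, kinds = c("V", "C"))
  h <- pm$hits[pm$hits$segment_name == "V1", ]
  pseq <- tPrimers()$seq[tPrimers()$primer_id == "PV1"]

  ## variant at the 3' terminus where the alternate allele equals a
  ## modified primer base: better match (+1)
  refBase <- substring(s, h$ref_end, h$ref_end)
  altBase <- setdiff(c("A", "C", "G", "T"), refBase)[1]
  pseqAlt <- paste0(substring(pseq, 1, 19), altBase)
  v <- list(position = h$ref_end, ref_allele = refBase, alt_allele = altBase)
  out <- assessVariant(v, h, pseqAlt, locus)
  expect_true(out$in_site)
  expect_equal(out$dist_from_3prime, 0L)
  expect_equal(out$match_delta, 1L)
  ## swapping ref and alt negates the delta
  vSwap <- list(position = h$ref_end, ref_allele = altBase,
                alt_allele = refBase)
  expect_equal(assessVariant(vSwap, h, pseqAlt, locus)$match_delta, -1L)
  ## with the true primer the same variant worsens the match
  expect_equal(assessVariant(v, h, pseq, locus)$match_delta, -1L)
  ## 12 bp from the 3' end: inside the site but outside the <= 10 window
  v12 <- list(position = h$ref_end - 12L,
              ref_allele = substring(s, h$ref_end - 12L, h$ref_end - 12L),
              alt_allele = "A")
  out12 <- assessVariant(v12, h, pseq, locus)
  expect_true(out12$in_site)
  expect_equal(out12$dist_from_3prime, 12L)
  ## outside every hit
  vOut <- list(position = h$ref_start - 50L, ref_allele = "A",
               alt_allele = "C")
  expect_false(assessVariant(vOut, h, pseq, locus)$in_site)
  expect_error(assessVariant(list(position = 10^7, ref_allele = "A",
                                  alt_allele = "C"), h, pseq, locus),
               "outside the locus")

  ## minus-strand hit: 3' end sits at ref_start
  hC <- pm$hits[pm$hits$segment_name == "C1", ]
  vC <- list(position = hC$ref_start,
             ref_allele = substring(s, hC$ref_start, hC$ref_start),
             alt_allele = "A")
  outC <- assessVariant(vC, hC, "GGGTGGGAACACCTTGTTCAGGT", locus)
  expect_true(outC$in_site)
  expect_equal(outC$dist_from_3prime, 0L)
})

test_that("allele-frequency filtering keeps any-positive variants, idempotently", {
  v <- data.frame(position = c(10, 20, 30, 40),
                  ref_allele = "A", alt_allele = "G",
                  segment_name = c("V1", "V2", "V3", "V4"),
                  Asian = c(0, 0, 0.5, 0),
                  East_Asian = c(0, 0.018, 0.1, 0),
                  Other_Asian = c(0, 0, 0, 0))
  out <- filterVariantsByFreq(v)
  expect_setequal(out$segment_name, c("V2", "V3"))
  expect_equal(out$max_freq[out$segment_name == "V2"], 0.018)
  expect_equal(out$max_freq[out$segment_name == "V3"], 0.5)
  ## idempotent
  again <- filterVariantsByFreq(out)
  expect_identical(again$max_freq, out$max_freq)
  expect_identical(again$segment_name, out$segment_name)
  ## missing population column: warned, treated as zero
  expect_warning(out2 <- filterVariantsByFreq(v[, -which(names(v) == "Asian")]),
                 "Asian")
  expect_true("V3" %in% out2$segment_name)  # still kept via East_Asian
  ## segment exclusion list
  out3 <- filterVariantsByFreq(v, segmentExclude = "V3")
  expect_setequal(out3$segment_name, "V2")
})
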