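## shared fixtures, built once per test run

.fixtures <- new.env()

tLocus <- function() {
  if (is.null(.fixtures$locus)) {
    .fixtures$locus <- buildSyntheticLocus(seed = 101)
  }
  .fixtures$locus
}

tSegTable <- function() {
  seg <- geneSegments(tLocus())
  data.frame(name = S4Vectors::mcols(seg)$name,
             kind = S4Vectors::mcols(seg)$kind,
             start = BiocGenerics::start(seg), end = BiocGenerics::end(seg),
             stringsAsFactors = FALSE)
}

## a small error-free two-sample cohort, built once
tCohort <- function() {
  if (is.null(.fixtures$cohort)) {
    set.seed(77)
    bcs <- makeBarcodes(2)
    samples <- data.frame(sample_id = c("S1", "S2"), barcode = bcs,
                          n_reads = c(200, 200))
    .fixtures$cohort <- simulateCohort(tLocus(), samples, seed = 202)
  }
  .fixtures$cohort
}

## the same cohort taken through preprocessing + annotation + labels
tPipeline <- function() {
  if (is.null(.fixtures$pipeline)) {
    coh <- tCohort()
    pp <- preprocessReads(coh$reads, coh$barcodes)
    ann <- annotateReads(pp$processed, tLocus())
    lab <- classifyReads(ann)
    .fixtures$pipeline <- list(cohort = coh, pp = pp, ann = ann, lab = lab)
  }
  .fixtures$pipeline
}

## construct a labelled segment row for classifier/chain tests
mkSeg <- function(read_start, read_end, ref_start, ref_end, strand = "+",
                  name = "I", kind = "I", upstream = 0L, matches = NULL) {
  len <- read_end - read_start + 1L
  data.frame(read_start = read_start, read_end = read_end,
             ref_start = ref_start, ref_end = ref_end, strand = strand,
             matches = if (is.null(matches)) len else matches,
             identity = 1, flags = "", name = name, kind = kind,
             upstream_intron_bp = upstream, stringsAsFactors = FALSE)
}
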