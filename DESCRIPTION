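Package: TRBrepertoire
Title: Classification of TCR-Beta 5'RACE Reads and Non-Recombined
    Transcript Biomarker Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for characterising T-cell receptor beta (TCRB) transcripts
    sequenced by 5'RACE amplicon sequencing. Reads are demultiplexed by dual
    barcodes, trimmed, aligned to an annotated TCRB-like locus, and classified
    into eight recombination/splicing categories (completely recombined,
    partially recombined, non-recombined, non-spliced, aberrantly spliced,
    aberrantly recombined, uncertain, chimeric). Downstream summaries cover
    per-sample category compositions, VJ-pairing and CDR3 clonotype tables
    with top-k dominance, J-gene usage, and the split of non-recombined J2-3
    reads into J2-2P-covering and J2-3-only subsets. A digital-PCR module
    computes the J2-2P~J2-3 to J2-3 concentration ratio, applies a 5% cutoff
    to call samples, and compares patient groups with an exact Wilcoxon
    rank-sum test. A synthetic locus builder and labelled read simulator
    provide ground truth for end-to-end validation, and a primer-audit module
    maps multiplex-PCR primers onto the locus and assesses variants falling
    in primer binding sites.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Sequencing, Alignment, Classification, ImmunoOncology
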