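---
title: "Classifying TCR-beta 5'RACE reads and the non-recombined J2-2P~J2-3 biomarker"
author: "TRBrepertoire"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying TCR-beta 5'RACE reads and the non-recombined J2-2P~J2-3 biomarker}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(TRBrepertoire)
```

## The problem

T-cell receptor beta (TCRB) transcripts amplified by 5'RACE capture far more
than the productive, completely recombined V(D)J messages that multiplex-PCR
clonality assays target. Because 5'RACE anchors only at the constant (C)
region, the sequenced reads also contain partially recombined D-J transcripts,
germline ("non-recombined", NR) J-C transcripts, unspliced C transcripts and
several classes of aberrant splicing and recombination. This package
implements, as a tested pipeline over a synthetic locus:

1. classification of every read into eight categories — CR, PR, NR, NS, AS,
   AR, UC, CH — from its chain of local alignments against the locus;
2. per-sample repertoire statistics: category compositions, VJ-pairing and
   CDR3-clonotype tables with top-k dominance, J-gene usage, and the split of
   NR J2-3 reads into those whose retained upstream intron covers the
   pseudogene J2-2P (`J2-2P~J2-3`) versus `J2-3_only`;
3. a digital-PCR biomarker module: the J2-2P~J2-3 to J2-3 concentration
   ratio, a 5% positivity cutoff, and an exact Wilcoxon rank-sum comparison
   of patient groups. The diagnostic idea is that T-cell lymphomas with a
   *polyclonal* TCRB pattern — invisible to V-J clonality assays — still shift
   the repertoire towards non-recombined transcripts, so the relative
   abundance of J2-2P~J2-3 messages separates TCL from non-TCL samples.

## The category model

A read's evidence is its *segment chain*: local alignments labelled by the
gene segment they overlap, ordered in transcript sense, plus bookkeeping
(upstream-intron lengths, unaligned head/tail, strand and reference-order
consistency over all alignments, number of C segments, distance from an
intergenic segment end to the nearest downstream cryptic 23RSS). Rules are
applied in precedence order; the first match wins:

| # | Category | Rule (thresholds in parentheses are configurable) |
|---|----------|---------------------------------------------------|
| 1 | CH | cross-strand segments, non-monotonic reference order, or ≥ 2 C segments |
| 2 | CR | ordered V-(D)-J-(C); V-(D)-only with unaligned tail ≤ 60 bp also CR, excluded from VJ/CDR3 statistics |
| 3 | PR | D-J-(C) with ≥ 15 bp intron immediately upstream of D; D-only with a tail, excluded from D-J statistics |
| 4 | AR | I-J-(C) whose intergenic segment ends ≤ 30 bp before a cryptic 23RSS start |
| 5 | AS | C concatenated downstream of V, D or I; plus I-J-(C) failing rule 4 |
| 6 | NR | J-(C) with ≥ 15 bp upstream intron |
| 7 | NS | C-only with ≥ 15 bp upstream intron and ≤ 120 bp unaligned |
| 8 | UC | everything else (J-(C) without the intron, C-only with a long unaligned segment, unmatched shapes) |

Boundary semantics are exact as stated: `>= 15`, `<= 60`, `> 120`, `<= 30`.
GT/AG splice motifs at chain junctions are recorded as *evidence* (reported
by `spliceEvidenceSummary()`), never as gating criteria: in real data they
are post-hoc support fractions, not filters. AR precedes AS because AR is
the more specific reading of an I-J-(C) chain. D-C chains are AS (the rule
lists V, D or intergenic donors); no separate PR-with-aberrant-splice class
exists. D-J-(C) chains whose D lacks the 15 bp intron are UC — their
recombination status is genuinely uncertain. For V-(D)-only chains the "read
ends within V" condition is subsumed by "tail ≤ 60 bp" (a read ending inside
V has tail 0), so the disjunction is implemented as the single tail bound.

Classification labels *reads*, not genes: an AS read may derive from a CR,
PR or NR transcript, so aberrant splicing does not reveal the underlying
recombination state, and the statistics treat the categories as
transcript-level descriptions.

## Annotation: from read to chain

Immune-locus annotation is implemented as generic local alignment plus
post-processing steps tailored to the TCRB locus:

* **Alignment** — exact 12-mer seeding against a hash index of the locus,
  clustering of seed hits by diagonal (break at diagonal jumps > 8 or read
  gaps > 40), X-drop extension (match +1, mismatch −3, drop 12), both
  strands. Clusters spanning several diagonals (indels) are refined with
  `Biostrings::pairwiseAlignment`. Segments shorter than 20 bp or below 85%
  identity are dropped: with 12-mer seeds this excludes spurious hits while
  keeping the 23 bp constant-primer region alignable. When the minus strand
  dominates, the read is reverse-complemented so a single canonical
  orientation is post-processed; the original orientation is metadata.
* **Homology dedup** — alignments overlapping ≥ 80% of the shorter read
  interval keep only the best-matching placement. This removes C1/C2
  ambiguity duplicates without discarding genuinely distinct placements
  (e.g. the two C segments of a chimeric C-J-C read).
* **Broken-alignment merging** (`mergeBroken`) — read-adjacent, same-strand
  alignments with both gaps in [0, 30] bp merge when the two gaps differ by
  less than half the larger gap; abutting pairs (0/0, where the strict
  inequality is undefined) merge, since fragmentation there is an alignment
  artefact. 30 bp is deliberately smaller than the smallest locus intron so
  real junctions can never merge. Applied to a fixpoint; merging runs before
  chain selection, on all segments.
* **C1→C2 reannotation** (`fixCOrder`) — the two C segments differ at a
  single base of the constant-primer window, so one sequencing error can
  flip the best alignment to the out-of-order C1; such segments are
  relabelled C2 with the homologous interval. The symmetric C2→C1 direction
  is never applied.
* **Splice-aware overlap splitting** (`splitOverlapAtSplice`) — read
  overlaps between neighbouring alignments are cut at a breakpoint where the
  upstream reference context ends before GT and the downstream begins after
  AG, choosing the match-count-maximising candidate; without a candidate the
  overlap splits at its midpoint and the pair is flagged
  `no_splice_support`. This also resolves the one-to-two-base boundary
  ambiguity that arises when an exon start happens to match the intron bases
  beyond a splice donor.
* **Chain selection** (`buildChain`) — dynamic programming picks the subset
  maximising total aligned read length under strand and strict
  reference-order consistency with non-overlapping read intervals; ties
  prefer more segments, then the leftmost read start, then the plus strand.
  Excluded segments are kept as conflicting evidence for chimera detection.
  For ≤ 4 segments the selection is verified against exhaustive subset
  enumeration in the test suite.

Alignments extending into the intron upstream of a gene segment keep the
gene label plus an `upstream_intron_bp` count — this is what makes the
15 bp intron rules decidable. Alignments overlapping only the pseudogene
J2-2P count as intergenic context; an NR read's J2-3 alignment that reaches
into J2-2P is detected by interval overlap (≥ 1 bp by default,
`minOverlap`) in `nrSubtypeSplit()`.

## The synthetic locus and read generator

The real TCRB locus and raw 454 data are not required: the package builds a
~4 kb TCRB-like locus with five V segments, two D-J-C clusters, the
pseudogene J2-2P immediately upstream of J2-3, and C1/C2 differing at one
base of the 23 bp constant-primer site. GT/AG motifs are planted at every
V/J donor and J/C acceptor; a cryptic 23RSS consensus sits 400 bp upstream
of D1, and recurrent intergenic splice donors 174 bp upstream of D1 and
150 bp upstream of D2. Intron lengths retained around segments default to
~100 bp (a free parameter; real annotation would fix them), and every
inter-segment gap is ≥ 30 bp so the ≥ 15 bp intron rules are exercisable.

Simulated inserts are built constructively so that perfect annotation
satisfies each category's defining rule; reads carry
adapter + 10 bp barcode + universal primer on the 5' end and the
reverse-complemented barcode + adapter on the 3' end, with uniform
substitution/indel errors. Generator defaults are the study conditions and
are not tuned: category mix CR 0.30, PR 0.06, NR 0.41, NS 0.06, AS 0.13,
AR 0.01, UC 0.02, CH 0.01 (NR the plurality, AS > PR, UC+CH ≈ 3%); NR J
usage skewed 70% to J2-3 with 76.2% of J2-3 introns covering J2-2P; V(D)J
junctions of 6–20 random bases; insert lengths roughly 150–400 bp,
454-like; AS donors default to the planted donor 174 bp upstream of D1 so
the modal-donor statistic is measurable. Clonal expansions are modelled as
a CR spike with fixed V/J/CDR3 at a set fraction of reads.

What the generator does **not** emulate: 454 flowgram/homopolymer error
structure, PCR length bias (shorter fragments amplifying more efficiently —
a known reason NGS and dPCR abundances differ), allele-level V diversity,
and real intron/RSS sequence context. Passing tests therefore demonstrate
that the *rules* are implemented correctly and recoverable under sampling
and substitution noise — not that real-data category fractions would be
reproduced.

## Digital-PCR biomarker

`computeRatio()` returns `100 * c(J2-2P~J2-3) / c(J2-3)`; reported values
are rounded half-up to one decimal, and `callSample()` is positive iff the
ratio is ≥ the 5% cutoff (boundary positive). `exactWilcoxon()` computes
the exact two-sided rank-sum p for tie-free samples up to n+m = 20 (from
the exact Mann-Whitney distribution, doubling the smaller tail and capping
at 1; a "minlike" two-sided variant is available), falling back to the
tie-corrected normal approximation otherwise. For the bundled 9-vs-6
cohort, complete separation gives exactly 2/C(15,6) = 2/5005 ≈ 0.0004.
BIOMED-2 negativity is parsed as "no monoclonal pattern in either TCR
gene" from the annotation text. Some printed ratios in the bundled table
are inconsistent with one-decimal recomputation from the printed
concentrations (the instrument evidently reported more decimals than
printed); the table therefore ships the printed ratios as authoritative
for cutoff and rank-sum computations, and ratio-reproduction tests target
only the self-consistent rows.

## Numerical and design choices

* Coordinates are 1-based closed (IRanges convention) internally and in
  GFF3 output.
* Demultiplexing assigns single-end-barcode reads by default (only
  *inconsistent* pairs must be discarded); `requireBothEnds = TRUE`
  restores the strict rule. A barcode call needs ≥ 8/10 matching bases;
  adapters tolerate ~10% mismatches.
* The trimmed-length filter is a sharp boundary: 150 bp kept, 149 dropped.
* Cryptic RSS sites are consumed from annotation; a consensus scan
  (heptamer CACAGTG + 23±1 bp spacer + nonamer ACAAAAACC, ≤ 2 mismatches)
  exists to audit the annotation, decoupling classification correctness
  from motif-scan heuristics.
* `dist_from_3prime` in the primer audit counts the 3'-terminal base as 0,
  so "within 10 bases of the 3' end" is `dist <= 10`. Primer matching is
  ungapped with a 4-mismatch budget; per segment the fewest-mismatch,
  leftmost hit is kept. Variant input is a TSV table (SNP discovery and
  dbSNP retrieval are out of scope); the frequency filter keeps variants
  with any positive frequency across the named populations and exposes a
  generic segment-exclusion list.

## Validation design and problem sizes

The test suite checks every rule at its boundary (intron 14/15/16, tail
59/60/61, unaligned 119/120/121, RSS distance 29/30/31), compares the
classifier against an independently coded predicate oracle on the
exhaustive enumeration of ≤ 4-segment templates crossed with those
boundaries, and verifies chain selection against subset enumeration on
1,000 random cases. End-to-end recovery uses 10,000-read cohorts (≥ 99%
per-category recall error-free, ≥ 90% at 1% substitutions, measured over
reads that survive preprocessing), parameter recovery pools 20 seeded
400-read cohorts (requested NR and J2-2P~J2-3 fractions within 3
multinomial σ of the pooled estimate; per-seed |z| < 4 — the pooled
reading tests the same property at higher power than per-seed bands, which
a correct implementation would still fail occasionally by chance), and a
50% clonal spike must surface as the top CDR3 clonotype within 3σ. These
sizes keep the whole suite within a coffee break on one CPU while leaving
every statistical band at ≥ 3σ.

## Limitations

Category labels are read-level descriptions; inferring the underlying DNA
recombination state would require paired DNA evidence. The aligner is
specialised to a single small reference (a few kb); it is not a general
read mapper. NGS-derived and dPCR-derived J2-2P~J2-3 abundances are not
directly comparable because of amplification length bias, which is exactly
why the biomarker module consumes dPCR concentrations rather than read
fractions.
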