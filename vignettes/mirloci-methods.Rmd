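---
title: "Discovering miRNA loci from small-RNA sequencing: methods and design"
author: "mirloci"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering miRNA loci from small-RNA sequencing: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirloci)
```

# The problem

Multi-tissue small-RNA sequencing yields hundreds of millions of short
reads, a mixture of mature microRNAs and their length isoforms (isomiRs),
PIWI-interacting RNAs in germline tissue, fragments of structural ncRNAs
(rRNA, tRNA, snoRNA), repeat-derived sequence and technical junk. The goal
of this package is to turn such libraries plus a reference genome into a
repertoire of miRNA *loci*: genomic intervals whose read stacks and
predicted secondary structure are consistent with processing of a
stem-loop precursor by Drosha and Dicer, together with a functional
annotation (known miRNA, other ncRNA, repeat, or novel), structural
placement (intergenic, intronic, exonic, UTR), expression profiles across
tissues, and cross-genome conservation.

The pipeline is desk-scale by design: every stage runs in minutes on a
laptop against synthetic data generated by the package itself, so each
stage is testable end to end without any external download.

# Pipeline stages and their parameters

## Cleaning and collapsing

Raw reads are 36 nt and contain the 3' sequencing adapter
(`ATCTCGTATGCCGTCTTCTGCTTG` by default). Trimming is a semi-global,
3'-anchored search: the adapter prefix is matched at every start position,
allowing mismatches up to `max_error_rate` (default 0.1, the standard
default of adapter trimmers) of the matched length, with a minimum overlap
of 3 nt. Among acceptable occurrences the best maximises matches minus
twice the mismatches, ties going to the leftmost occurrence. Reads with no
detectable adapter are kept if they pass the filters and reported
separately — at 36 nt raw length they exceed the length cap anyway, so the
choice only matters for shorter raw reads.

After trimming, inserts must be 16-28 nt inclusive, contain no N, and use
at least three distinct nucleotides ("low complexity" is interpreted as
these sequence-content filters; no base-quality threshold is applied
anywhere, which is why the generator emits constant quality strings).
Surviving reads are collapsed to unique sequences with one count per
library and a pooled count summed over all libraries; sequences whose
pooled count falls below `min_pooled_count` are removed. The
production-scale default is 1000; synthetic runs scale it to 10, keeping
the ratio of threshold to library depth comparable.

## Mapping and locus building

Unique sequences are placed on the genome by exact, full-length matching
on both strands. A sequence with more than `max_hits` (default 15) total
occurrences is treated as repeat-derived and excluded entirely — the
conservative reading of a reporting cap, since a cap that silently
truncates hits would distort locus building. Placements on the same
chromosome and strand separated by at most `merge_gap` nt (default 70,
inclusive: a 70-nt gap merges, 71 splits) are merged into loci by a single
sorted sweep; the merge is the connected-component closure of the pairwise
relation, verified in the tests against a quadratic union-find.

## Folding

Candidate precursor windows (lengths 50-90 nt, length step 2, position
step 3, always containing the dominant read stack, clipped at chromosome
ends) are folded by a purpose-built dynamic program restricted to the
single-stem-loop structure class: one ladder of nested pairs closed by a
terminal loop of 3-20 nt, at most 4 unpaired bases per side between
consecutive pairs. Pairs score GC = 3, AU = 2, GU = 1; an interior loop
event costs 4 plus 1 per unpaired base. The maximum-score structure is a
stability proxy (`mfe_proxy` is its negation); a window is foldable when
the best structure holds at least `min_stem` = 16 pairs. A thermodynamic
folding engine could replace this component behind the same contract, but
the pipeline needs only stem-loop detection and comparable scores, and
the restricted dynamic program is exactly enumerable — the test suite
checks it against an exhaustive independent recursion on hundreds of
random sequences.

## Scoring

Prediction evaluates five criteria — stem-loop structure, precursor
size, loop sizes, dominant-read size and placement on the stem, and the
expression profile — combined into a composite score on a 0-1300 scale
with 800 as the high-confidence threshold. The point allocation is this
package's own design, with all weights exposed in `scoring_config()` and
the following anchors treated as the contract: a canonical archetype
(clean 28-bp stem, 22-nt dominant read on one arm, 85% shared 5' ends,
star reads present) scores at least 800; the same locus with a 27-nt
dominant read falls below 800; scattered-read non-hairpin loci mostly
fall below 250; and a base-shuffled genome with randomly placed reads
yields no high-confidence prediction.

The five criteria (maxima 400/100/100/550/150, total 1300):

1. **Structure (400)** — the product of three ramps: stem length (14
   pairs scores 0, 28 full), fraction of window positions paired (0.5 to
   0.85), and a clean-stem factor that decays once the structure needs
   more than 2 interior-loop events (zero at 6). The third factor is what
   separates real hairpins from random sequence, which reaches high pair
   counts only by zig-zagging through many interior loops.
2. **Precursor size (100)** — full inside 60-80 nt, linearly decaying to
   zero 20 nt outside.
3. **Loop geometry (100)** — starts full and loses 30 points per interior
   loop larger than 3 nt, 25 if the terminal loop leaves 3-15 nt, and 5
   per event beyond the second; the result is scaled by the stem-length
   ramp so short chance stems cannot collect full geometry credit.
4. **Dominant read (550)** — all-or-ramp: the most-represented sequence
   must be 20-24 nt with at least 90% of its span on one stem arm, its
   pairing path must be duplex-like (at most 2 interior events, none
   larger than 2 nt summed over both sides, at most 2 G:U wobbles), and
   the points then ramp with the paired fraction of the read span (0.6 to
   0.85). The duplex gates encode how Dicer substrates look: point
   substitutions between arms open size-2 loops and single wobbles,
   whereas chance duplexes in random sequence lean on larger asymmetric
   loops and a heavy wobble load (measured on shuffled genomes: 19-27%
   wobbles versus under 9% for planted hairpins).
5. **Expression (100 + 50)** — processing precision: a graded credit
   (0.5 to 0.8 ramp) for the count-weighted fraction of locus reads
   sharing the dominant 5' end, granted only when the locus has at least
   two distinct sequences; plus 50 points when any read sits
   predominantly on the opposite arm (star support). Star reads are
   rewarded, not required.

The dominant-read weight is deliberately the largest: the composite must
drop below 800 when only that criterion fails (the 27-nt anchor), which
forces its weight above 500 on this scale. One prediction is kept per
locus — the best-scoring window, ties broken by longer stem, then length
closest to 70 nt, then leftmost. Confidence is `high` iff score >= 800
(inclusive).

```{r archetype}
hp <- paste0("GCGGCAUUGCAUCCAGGCUAAGCGCAGG", "GAAUAA",
             "CCUGCGCUUAGCCUGGAUGCAAUGCCGC")
fold_hairpin(hp)
```

## Annotation

Known-miRNA databases from two sources are merged with provenance
(both / first-only / second-only), collapsing identical sequences.
Precursors are compared with each non-repeat database by local alignment
on both strands; a hit needs identity at least 0.9 over at least 0.8 of
the shorter sequence — thresholds chosen to accept cross-species mature
conservation while rejecting chance 8-mers, and exposed as parameters.
Repeat
elements are matched separately and require a perfect full-length
occurrence. The functional partition applies the precedence repeat >
other-ncRNA > miRNA-multi > miRNA-only > novel; predictions with both
repeat and other-ncRNA evidence are counted once in the discard pool with
the overlap reported.

Structural classification intersects each locus with gene models under
the precedence UTR > exon > intron > intergenic, ignoring gene-model
strand: the partition has no antisense category, so genic overlap on
either strand counts as genic. Percentages are half-up rounded to one
decimal.

## Expression

Count matrices are built per isomiR (one row per assigned unique
sequence) or per locus (member counts summed), with counts-per-million
computed over each library's own matrix total. For clustering, the scale
is log2(CPM + 1) — standard for count heatmaps and robust to the strong
family dominance of miRNA data — then
rows are median-centered, the distance is 1 minus Pearson correlation,
and linkage is average. Rows and columns are sorted by id before
clustering so leaf order is deterministic and input-order invariant.
qPCR validation consumes already-normalised relative abundances and
reports per-miRNA Pearson correlations of log-transformed paired values
over shared tissues (at least 3).

## Conservation

Presence of each mature in a panel genome means at least one ungapped
occurrence with at most `max_mismatch` substitutions (default 2) on
either strand — the minimal reading of "hits and eventual mismatches
recorded". The summary reports the breadth distribution (how many matures
are found in k panel genomes) and per-genome presence percentages.

# The synthetic study

`sim_genome()` plants, by default, 20 precursors (60-80 nt, arms 26-30 nt
with up to 2 substitutions in the 3' arm, terminal loops 6-12 nt) into 3
chromosomes of 50 kb, 80% intergenic / 15% intronic / 5% exonic against
toy gene models, at least 200 nt apart; every precursor is verified
foldable before emission so recovery tests are well-posed. 70% of
hairpins enter the known-miRNA databases (split 60/20/20 between
both/first/second source to exercise provenance); the remainder exercise
the novel path. Decoy rRNA/tRNA/snoRNA elements and two repeat elements
(one at 18 copies to trip the repetitiveness cap, one at 2 to reach the
annotation stage) are planted as well; decoys carry an embedded hairpin
so the loci built on their fragments actually fold and reach annotation,
as real structural-ncRNA fragments do.

Expression assigns the two dominant families about 30% and 15% of pooled
signal (the strong two-family skew typical of miRNA data) and makes them
ubiquitously expressed, as top families are in real multi-tissue
datasets; their matures are canonical 22-mers. Remaining loci are 40%
tissue-specific, 30% tissue-predominant, 30% ubiquitous, with mature
lengths drawn from a distribution peaking sharply at 22 nt. Per-library
counts are Poisson around the configured expectations.

`sim_library()` writes 36-nt raw reads: isomiR inserts (independent 5'
and 3' end shifts: 0 with probability 0.6, +/-1 with 0.3, +/-2 with 0.1;
10% of locus reads from the star arm) plus adapter, truncated to the raw
length. Gonadal libraries add a 26-28-nt piRNA-like population (45% of
reads, mode 27 — drawn from random genome positions, so nearly all of it
falls under the pooled-count threshold, as dispersed piRNA reads do under
a global threshold) giving the bimodal 22/27 length histogram; somatic
libraries are unimodal at 22. Noise (10%) consists only of reads the
filters reject — homopolymer-like, N-containing, and adapter-free 36-mers
— so the rejected fraction estimates the noise rate; decoy ncRNA
fragments are a separate 5% component drawn with heavy reuse so they
survive thresholding and form annotatable loci.

What the generator does *not* emulate: sequencing errors and quality
realism, ligation/PCR bias, genuine piRNA clusters, heteroduplex arms
from paralogous loci. Passing recovery tests on this generator therefore
demonstrates the pipeline's logic — trimming, collapsing, mapping,
merging, folding, scoring, partitioning — not robustness to base-call
error or bias, which the upstream study handled with depth and the
pooled-count threshold.

# Numerical choices and degenerate inputs

* Coordinates are 0-based half-open internally, BED on output, 1-based
  only in GFF interactions.
* T and U are equivalent everywhere; folding and scoring are
  deterministic for fixed inputs, with all ties broken by fixed rules
  (documented above) rather than input order.
* Empty inputs (no reads, no hairpins, empty databases) return empty,
  well-typed results rather than errors; a zero total in a percentage
  table is an error.
* `round_half_up()` is used for printed percentages so x.x5 rounds away
  from zero, matching conventional reporting rather than banker's
  rounding.
* Problem sizes used by the validation suite: 6 libraries of 50,000
  reads over a 150-kb genome with 20 planted hairpins for recovery and
  the shuffled-genome control; 200 randomized fixtures per brute-force
  oracle; 20 seeds for the length-mode check. These sizes keep each
  property estimable with comfortable margins while the whole suite runs
  in minutes.

# Known limitations

* The composite score's absolute values are conventions of this
  package; only the ordering of predictions and the threshold semantics
  are meaningful, and scores from other hairpin-prediction tools are not
  directly comparable.
* The folder cannot represent multi-branch or pseudoknotted structures,
  mirtrons, or bulged Drosha sites beyond the bounded interior loops.
* Database search is local alignment at toy scale; no e-value model.
* A shuffled genome can, rarely, contain a genuine hairpin with a
  well-placed read; the duplex gates make such false high-confidence
  calls very unlikely, but no criteria-based scorer can make them
  impossible in principle.
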