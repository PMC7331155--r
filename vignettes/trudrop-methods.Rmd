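---
title: "Dual-indexed inDrop library design: models and methods"
author: "TruDropDesign"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-indexed inDrop library design: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(TruDropDesign)
```

## Background

Droplet single-cell RNA-seq libraries built on the inDrop V2 design are
single-indexed and use custom sequencing primers. Both properties become
liabilities on sequencers that cluster by exclusion amplification (ExAmp)
on patterned flow cells (NovaSeq, iSeq, HiSeq 3000/4000/X): free adapter
molecules misprime library strands and physically swap sample indexes
("index hopping"), and the custom V2 index primer cross-reacts with the
standard Illumina primers that dominate shared runs. The TruSeq-inDrop
(TruDrop) redesign moves the library onto standard TruSeq adapters with a
unique dual index pair per sample, so hopped reads surface as unanticipated
(i7, i5) combinations and can be filtered during demultiplexing.

This package implements the computational side of that design space:
library-structure templates and primer derivation, mispriming screens,
index-set validation, the cross-sample barcode-collision model, a pooled-run
simulator with index hopping, an inDrop barcode-read parser, and the
sequencing-quality statistics used to compare runs.

## Library structures and primers

Three presets (`getStructure("TRUSEQ" | "INDROP_V2" | "TRUDROP")`) store the
published template strings segment by segment. Fixed segments (adapters,
priming sites, the 22-base W1 spacer `GAGTGATTGCTTGTGACGCCTT`, the 19-base
poly-T stretch) are verbatim; sample indexes (6--10 bases), cell barcode 1
(8--11 bases), cell barcode 2 (8), the UMI (6) and the insert are
placeholders with length ranges. `renderTemplate()` reproduces the printed
strings; the `"spaced"` placeholder dialect matches the conventional
printed layout (templates are compared after whitespace normalization and
case-folding of tokens, because printed templates mix both).

Read primers are taken to equal their priming-site sequences, and
index-read primers to be the reverse complement of the priming site
flanking the index -- the standard Illumina convention; the templates
themselves never print index primers. Under this rule the V2 i7 index
primer (reverse complement of the truncated site
`CTCTTTCCCTACACGACGCTCTTCCGATCT`) and the standard TruSeq index primer
share exactly 13 5'-terminal bases (`AGATCGGAAGAGC`), which is the
documented mispriming hazard between V2 and standard libraries on shared
runs.

`misprimingReport()` scores, for each read role declared by both
structures, the longest shared 5' prefix of the two primers, flagging pairs
at or above a threshold (default 13, the observed hazard length). The
comparison is deliberately restricted to *same-role* primer pairs: primers
for the same read are the ones present in the flow cell during the same
sequencing step, so only they can compete for a cluster. Comparing across
roles would flag every index1/index2 primer pair (both R1- and R2-type
priming sites end in `GCTCTTCCGATCT`), a shared chemistry motif rather
than a hazard. Only exact prefix identity is scored; thermodynamic
annealing models are out of scope.

## Index sets and hop filtering

`validateIndexSet()` checks each side of a sample sheet independently for
pairwise Levenshtein distance at or above 2 (the criterion published index
sets satisfy, so that a single insertion, deletion or substitution cannot
convert one index into another), reports mixed index lengths within a side,
and warns when the scheme is not unique-dual. The edit distance is
`utils::adist()`, the standard dynamic program.

`assignReads()` matches each observed index to the unique sheet index
within a Hamming tolerance (default 1 mismatch, mirroring common
demultiplexer behavior; the tolerance interacts safely with distance-2
index sets only when a *unique* match is required, so ambiguous matches are
`undetermined`). For dual sheets, an anticipated (i7, i5) combination
assigns the read; two matched indexes in an unanticipated combination mean
the read hopped and it is filtered; single-index sheets use i7 alone and
can never detect a hop. A read whose two indexes both hop onto the same
foreign sample's pair is indistinguishable from a legitimate read and is
mis-assigned -- this is a property of the scheme, not of the
implementation, and the simulator reproduces it.

## Cross-sample barcode collision

With `k` pooled cells drawing barcodes uniformly and independently from a
space of `N` barcodes, the probability that a given cell shares its barcode
with at least one other cell is `1 - (1 - 1/N)^(k - 1)` (the exponent
excludes the focal cell; using `k` instead changes the result by under
1e-4 at default scales). Because hopping makes every read equally likely to
claim any pooled sample, all cells are treated as one pool. Collision and
hopping are modeled as independent per-cell events and combined by
inclusion-exclusion:

    P(discard) = P(collision) + h - P(collision) * h

Defaults are 3000 cells per sample (the encapsulation target), hop rate
`h = 0.0485` (the documented NovaSeq hopping rate) and `N = 147456 = 384 x
384`, the inDrop V2 split-barcode combinations. `N` is never printed in the
published analysis; this value reproduces the published 8.67% discard for a
pool of two samples to within 0.03 percentage points (the analytic value is
8.64%), and it is a parameter, not a constant. The published percentages
for larger pools (15.99, 26.19, 43.87% against five pool sizes) cannot be
mapped one-to-one to parameters -- the original supplementary calculation
is not printed -- so beyond the pool of two the model is validated by its
monotonicity and bounds (`max(P_c, h) <= P(discard) <= P_c + h`) and by
Monte Carlo agreement (`mcDiscard()`, which simulates whole pools and
counts duplicated-or-hopped cells; agreement within three standard errors
is part of the test suite).

## The pooled-run simulator

`simulatePool()` generates ground-truth reads: the barcode read is
barcode 1 + W1 + barcode 2 + UMI + poly-T fill, the transcript read is
random sequence. Default read lengths follow the published run
configurations (V2 on NextSeq: 100-cycle transcript read, 6-cycle index
read, 50-cycle barcode read; TruDrop: paired 150-cycle reads with 8-cycle
index reads).

Hop mechanics: hopping is described mechanistically as a free adapter
mispriming one end of a molecule, i.e. one index swaps at a time. Each
index side therefore hops independently with probability `h/2` (total
per-read hop probability `1 - (1 - h/2)^2`, close to `h` for small rates),
with the destination drawn uniformly from the other samples' indexes on
that side -- no destination distribution is documented, and uniformity is
the natural null. Single-indexed sheets put the whole budget `h` on i7.
Two consequences worth stating explicitly, since both are asserted by the
test suite: single-side hops dominate and are *always* filtered by a
unique-dual sheet; and when the same dual-indexed reads are demultiplexed
on i7 alone, the mis-assignment rate equals the i7-side rate `h/2`, not
`h`, because i5-only hops are invisible in that mode.

Qualities default to constant Q37; a per-cycle decay profile
(`list(type = "profile", mean = , sd = )`) is available for parameter-
recovery tests. Index reads are written error-free: the simulator models
hopping and pooling, not base-calling noise, so "percent perfect index
reads" is 100% on simulated data and is meaningful only on real inputs.
Other aspects of real runs that are deliberately not emulated: cluster
optics and over-clustering, non-uniform barcode usage across bead lots,
PhiX spike-ins, and sequencing errors inside barcode or index reads.
Passing tests therefore validate the demultiplexing logic and the
collision arithmetic, not robustness to read errors.

In cell mode (`cellsPerSample` set) each sample first draws that many
cells from a finite (bc1, bc2) space and reads then sample cells, which is
the regime of the collision model. `singleIndexCollisionLoss()` implements
the computational countermeasure available to single-indexed pools:
discard any barcode observed in two or more samples' retained reads. Note
its structural limits -- within-sample collisions are invisible (two cells
with the same barcode in one sample look like one cell), and a hopped read
from a single-read cell relocates its barcode rather than duplicating it
-- so the observable discard fraction sits below the pool-level analytic
`pDiscard()`; the test suite validates the rule against an independent
tally of cross-sample barcode intersections instead.

Determinism: a seed fully reproduces a simulation, including byte-identical
FASTQ output (Phred+33, indexes in I1/I2 files and in the header comment).

## Barcode-read parsing

`parseBarcodeReads()` anchors the W1 spacer by Hamming distance (no
indels) at offsets 8--11, the admissible barcode-1 lengths; the offset with
the fewest mismatches wins, ties to the smallest offset. The default
tolerance of 2 mismatches in a 22-base spacer stays well below half the
typical whitelist distance, so mis-anchoring cannot silently reassign
barcodes. Failures return invalid records with a diagnostic
(`too_short`, `w1_not_found`, whitelist misses), never an error, because a
parser that throws on the first bad read is useless on real files. The
barcode-1 range 8--11 is exposed as a parameter: it is implied by the
50-cycle barcode read (8 + 22 + 8 + 6 = 44 cycles minimum, leaving the
final ~6 cycles reading into the poly-A/T tail) rather than printed
directly.

`regionMap()` returns the published cycle layouts as 0-based half-open
intervals. One documented quirk: the published barcode-read QC intervals
(cycles 1--11 and 31--50, 1-based) treat the spacer as cycles 12--30, i.e.
19 cycles, although W1 is 22 bases long. The QC presets follow the printed
intervals; parsing follows the 22-base spacer. Both are kept, and the
discrepancy is intentional.

## Quality statistics

`perCycleQuality()` computes per-cycle mean Phred scores and the fraction
of bases at or above a threshold (Q30 by default), with ragged reads
contributing only to the cycles they cover. `regionMeanQuality()` weights
per-cycle means by per-cycle base counts, which reduces to a plain mean for
uniform-length reads; the transcript region of 150-cycle runs is scored on
its first 100 cycles for comparability with 100-cycle runs. Error
probabilities follow `p = 10^(-Q/10)`. Published error probabilities are
close to but not exactly the transform of published mean qualities,
implying an unstated order of averaging (average Q then transform, or
transform per cycle then average); both orders are available by composing
`qToError()` with either the region mean or the per-cycle vector, and
fold-change comparisons (`errorFoldChange()`) operate on whichever
probabilities the user supplies.

The exact Mann-Whitney test (`mannWhitneyExact()`) computes the null
distribution from the count recurrence
`N(u; m, n) = N(u - n; m - 1, n) + N(u; m, n - 1)`, equivalently the
number of partitions of `u` into at most `min(m, n)` parts of size at most
`max(m, n)`. Counts are accumulated in double precision, which is exact
here (all counts stay far below 2^53 for the group sizes of interest), so
p-values on the 1e-9 scale are exact until the single final division. The
two-sided p is twice the smaller tail, clamped at 1, with no mid-p
correction -- the convention that reproduces the published quality-score
comparisons. Ties are refused rather than approximated: the exact
distribution assumes none, and the companion `mannWhitneyU()` computes the
statistic from raw samples (U = number of pairs with group-1 value below
group-2 value) only when all values are distinct. A normal approximation
with continuity correction is provided for large groups. One published
p-value (U = 49, n1 = 21, n2 = 11) is not consistent with the exact
no-ties rule that reproduces the other three; the exact method is retained
unchanged, and the corresponding check in the test suite records the
discrepancy rather than papering over it.

`percentOfTarget()` rounds half-up to one decimal, matching the printed
percentage convention.

## Problem sizes and numerical choices

The test suite and acceptance script run at desk scale by design: hop
simulations use 1e5 reads (enough to pin a 4.85% rate within three
binomial standard errors of a fraction of a percent), the Monte-Carlo
collision check uses 200 pools of 6000 cells (1.2 million cells), and the
exact Mann-Whitney distribution is verified against brute-force label
enumeration for all group sizes with n1 + n2 <= 14. Statistical assertions
use three-standard-error bands under fixed seeds. Degenerate inputs are
defined rather than accidental: empty pool-size lists give empty tables,
a single-sample sheet refuses to hop (there is no foreign index), zero
reads give an empty stream, and invalid barcode reads come back as flagged
records.

## Worked example

```{r example, eval = FALSE}
sheet <- SampleSheet(c("Mouse4", "Mouse5"),
                     i7 = c("CCGCGGTT", "TTATAACC"),
                     i5 = c("AGCGCTAG", "GATATCGA"))
validateIndexSet(sheet)          # 0 rows: distance >= 2, unique dual

reads <- simulatePool(sheet, getStructure("TRUDROP"),
                      readsPerSample = 50000, hopRate = 0.0485, seed = 1)
dual <- demultiplex(reads, sheet)
scoreDemux(dual$assignments)     # hop capture ~ 1 for single-side hops

100 * pDiscard(PoolConfig(nSamples = 2))   # 8.64% discard for a pool of 2
pValue(mannWhitneyExact(0, 26, 11))        # 2.339e-9
```

## Limitations

The package computes on simulated or user-supplied FASTQ; it does not
reproduce published run-level quality tables, which derive from sequencer
data. Index-set validation implements the edit-distance criterion only;
designing new index sets and whatever additional per-pair wet-lab
validation a vendor applies are out of scope, as are BCL handling,
alignment, UMI counting and downstream single-cell analysis.
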