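# TruDropDesign

Toolkit for the dual-indexed TruSeq-inDrop (**TruDrop**) single-cell
RNA-seq library design and for the failure modes it was designed around:
**index hopping** on patterned-flow-cell sequencers (NovaSeq/iSeq/HiSeq
ExAmp chemistry), **cross-sample cell-barcode collision** in single-indexed
pools, and **sequencing-primer mispriming** between custom inDrop V2
primers and standard Illumina primers.

It is intended for people who design, pool and demultiplex droplet
scRNA-seq libraries and want to reason quantitatively about index schemes
before committing a flow cell.

## What it computes

- **Library structures** — the TruSeq, inDrop V2 and TruDrop templates as
  segment-level presets (`getStructure()`, `renderTemplate()`), sequencing
  primers derived by the standard convention (read primers equal their
  priming sites; index primers are the reverse complement of the adjacent
  site, `deriveSequencingPrimers()`), and a mispriming screen
  (`misprimingReport()`). The V2 and TruSeq index-read primers share a
  13-base 5' region — the documented hazard on shared runs.
- **Index sets** — scheme classification (single / combinatorial dual /
  unique dual), pairwise edit-distance validation (minimum 2 on each side,
  `validateIndexSet()`), and hop-aware read assignment: anticipated (i7,
  i5) combinations are assigned, unanticipated ones are filtered as hopped
  (`assignReads()`).
- **Collision model** — the fraction of cell barcodes that must be
  discarded from a single-indexed pool. With `k` pooled cells over `N`
  barcodes and a per-cell hop rate `h`:

  `P(collision) = 1 − (1 − 1/N)^(k−1)`,
  `P(discard) = P(collision) + h − P(collision)·h`

  (defaults: 3000 cells/sample, `N = 384² = 147456`, `h = 0.0485`), plus a
  Monte-Carlo cross-check (`pDiscard()`, `discardCurve()`, `mcDiscard()`).
- **Hop simulator** — pooled runs with ground truth, per-side hopping,
  FASTQ output, demultiplexing and scoring (`simulatePool()`,
  `writeFastq()`, `demultiplex()`, `scoreDemux()`,
  `singleIndexCollisionLoss()`).
- **Barcode-read parser** — variable-length barcode 1, the 22-base W1
  spacer, barcode 2, UMI and poly-T from inDrop barcode reads
  (`parseBarcodeReads()`), and published cycle-region maps
  (`regionMap()`).
- **Quality statistics** — per-cycle Q30 fractions, region-weighted mean
  quality, Phred error probabilities `p = 10^(−Q/10)`, fold changes, and
  an exact Mann-Whitney U test built on the partition-count recurrence
  (`perCycleQuality()`, `regionMeanQuality()`, `mannWhitneyExact()`,
  `percentOfTarget()`).

## Worked example

```r
library(TruDropDesign)

# the two published dual-indexed samples
sheet <- SampleSheet(c("Mouse4", "Mouse5"),
                     i7 = c("CCGCGGTT", "TTATAACC"),
                     i5 = c("AGCGCTAG", "GATATCGA"))
indexScheme(sheet)            # "unique_dual"
nrow(validateIndexSet(sheet)) # 0 — edit distance >= 2 on both sides

# simulate a pooled NovaSeq-like run at the documented 4.85% hop rate
reads <- simulatePool(sheet, getStructure("TRUDROP"),
                      readsPerSample = 50000, hopRate = 0.0485, seed = 1)
demultiplex(reads, sheet)$report
#> DemuxReport: 100000 reads (95106 assigned, 4894 hop-filtered, 0 undetermined)
#>   percent perfect index reads: 100.00%
#>   misassignment rate: 0.00057
```

The unique-dual filter catches every single-side hop (the 4894 filtered
reads); the residual 0.06% mis-assignment is exclusively double hops that
land on another sample's anticipated pair — undetectable by any indexing
scheme. The same reads demultiplexed on i7 alone (`ignoreI5 = TRUE`)
mis-assign at the full i7-side hop rate instead.

```r
# discard fraction for a single-indexed pool of 2 x 3000 cells
100 * pDiscard(PoolConfig(nSamples = 2))
#> [1] 8.6433
mcDiscard(PoolConfig(2), nPools = 200, seed = 1)
#> CollisionEstimate
#>   analytic: P(collision) = 0.039867, P(discard) = 0.086433
#>   Monte Carlo: 0.086659 +/- 0.000275 (SE; 1.2e+06 cells, seed 1)

# the mispriming hazard that motivated the redesign
misprimingReport(getStructure("INDROP_V2"), getStructure("TRUSEQ"))[
  , c("role", "sharedPrefix", "flagged")]
#>     role sharedPrefix flagged
#> 1  read1            0   FALSE
#> 2  read2            0   FALSE
#> 3 index1           13    TRUE

# exact Mann-Whitney comparison of 26 vs 11 library quality scores
pValue(mannWhitneyExact(0, 26, 11))
#> [1] 2.339203e-09
```

So: ~8.6% of cells would be discarded from even a two-sample
single-indexed pool, the V2 index primer shares 13 of its first 13 bases
with the standard index primer, and a U = 0 separation of 26 vs 11
quality scores has a two-sided exact p of 2.3e-9.

## Command line

A thin CLI over the same functions ships in `inst/scripts/trudrop-cli.R`
(subcommands `check-structure`, `validate-indexes`, `collide`, `simulate`,
`demux`, `parse`, `qc`, `mwu`), e.g.

```sh
Rscript inst/scripts/trudrop-cli.R collide --samples 2,4,12,24,48
Rscript inst/scripts/trudrop-cli.R mwu --u 0 --n1 26 --n2 11
```

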