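#' @import methods
NULL

.DNA_ALPHABET <- c("A", "C", "G", "T", "N")

.validDNA <- function(x, allowN = TRUE) {
  pat <- if (allowN) "^[ACGTN]+$" else "^[ACGT]+$"
  grepl(pat, x)
}

#' LibraryStructure: a sequencing library template
#'
#' Ordered sequence segments for the P5 and P7 sides of a library, plus the
#' mapping from sequencing reads (read1/read2/index1/index2) to the regions
#' they cover and the priming sites they prime from. Segments are rows of a
#' data frame with columns `label`, `role` (one of flowcell_adapter,
#' sample_index, priming_site, cell_barcode, spacer, umi, polyT, insert),
#' `sequence` (DNA for fixed segments, `NA` for placeholders) and
#' `minLen`/`maxLen`.
#'
#' Use [getStructure()] to obtain the built-in TRUSEQ, INDROP_V2 and TRUDROP
#' presets rather than constructing objects by hand.
#'
#' @slot name structure name.
#' @slot p5Side,p7Side segment data frames, ordered 5' to 3'.
#' @slot readRoles named list; each entry has elements `covers` (segment
#'   labels the read sequences through) and `primingSite` (label of the
#'   priming-site segment the read primes from).
#' @aliases LibraryStructure
#' @export
setClass("LibraryStructure",
  representation(
    name = "character",
    p5Side = "data.frame",
    p7Side = "data.frame",
    readRoles = "list"
  )
)

.segmentColumns <- c("label", "role", "sequence", "minLen", "maxLen")
.segmentRoles <- c(
  "flowcell_adapter", "sample_index", "priming_site", "cell_barcode",
  "spacer", "umi", "polyT", "insert"
)

.validateSegments <- function(seg, what) {
  if (!all(.segmentColumns %in% names(seg))) {
    return(sprintf("%s must have columns %s", what,
                   paste(.segmentColumns, collapse = ", ")))
  }
  bad <- !seg$role %in% .segmentRoles
  if (any(bad)) {
    return(sprintf("%s: unknown role(s) %s", what,
                   paste(unique(seg$role[bad]), collapse = ", ")))
  }
  fixed <- !is.na(seg$sequence)
  if (any(fixed) && !all(.validDNA(seg$sequence[fixed]))) {
    return(sprintf("%s: fixed segments must contain only A/C/G/T/N", what))
  }
  if (any(!fixed & (is.na(seg$minLen) | is.na(seg$maxLen)))) {
    return(sprintf("%s: placeholder segments need a length range", what))
  }
  if (any(seg$minLen > seg$maxLen, na.rm = TRUE)) {
    return(sprintf("%s: minLen > maxLen", what))
  }
  TRUE
}

setValidity("LibraryStructure", function(object) {
  msgs <- character(0)
  for (side in c("p5Side", "p7Side")) {
    v <- .validateSegments(slot(object, side), side)
    if (!isTRUE(v)) msgs <- c(msgs, v)
  }
  labels <- c(object@p5Side$label, object@p7Side$label)
  known <- c("read1", "read2", "index1", "index2")
  for (rn in names(object@readRoles)) {
    if (!rn %in% known) {
      msgs <- c(msgs, sprintf("unknown read role '%s'", rn))
      next
    }
    role <- object@readRoles[[rn]]
    refs <- c(role$covers, role$primingSite)
    miss <- setdiff(refs, labels)
    if (length(miss)) {
      msgs <- c(msgs, sprintf("read role '%s' references missing segment(s): %s",
                              rn, paste(miss, collapse = ", ")))
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' PrimerSet: sequencing primers derived from a library structure
#'
#' @slot read1,read2,index1,index2 primer sequences (`NA_character_` when the
#'   structure declares no such read, e.g. index2 for single-indexed designs).
#' @slot structure name of the structure the primers were derived from.
#' @aliases PrimerSet
#' @seealso [deriveSequencingPrimers()]
#' @export
setClass("PrimerSet",
  representation(
    read1 = "character", read2 = "character",
    index1 = "character", index2 = "character",
    structure = "character"
  )
)

#' SampleSheet: per-sample index pairs
#'
#' Holds one i7 (and optionally i5) sample index per sample together with the
#' derived indexing-scheme classification: `single` (no i5), `unique_dual`
#' (no index reused on either side) or `combinatorial_dual` (some index
#' repeated on one side). Construct with [SampleSheet()] or
#' [readSampleSheet()].
#'
#' @slot entries data frame with columns `sampleId`, `i7`, `i5`
#'   (`NA` for single-indexed sheets).
#' @slot scheme cached scheme label.
#' @aliases SampleSheet-class
#' @export
setClass("SampleSheet",
  representation(entries = "data.frame", scheme = "character")
)

setValidity("SampleSheet", function(object) {
  e <- object@entries
  msgs <- character(0)
  if (!all(c("sampleId", "i7", "i5") %in% names(e))) {
    return("entries must have columns sampleId, i7, i5")
  }
  if (nrow(e) < 1L) msgs <- c(msgs, "sheet needs at least one entry")
  if (anyDuplicated(e$sampleId)) msgs <- c(msgs, "sample ids must be unique")
  if (any(is.na(e$i7)) || !all(.validDNA(e$i7, allowN = FALSE))) {
    msgs <- c(msgs, "i7 indexes must be non-empty sequences over A/C/G/T")
  }
  hasI5 <- !is.na(e$i5)
  if (any(hasI5) && !all(hasI5)) {
    msgs <- c(msgs, "i5 must be present for all samples or for none")
  }
  if (any(hasI5) && !all(.validDNA(e$i5[hasI5], allowN = FALSE))) {
    msgs <- c(msgs, "i5 indexes must be sequences over A/C/G/T")
  }
  if (!object@scheme %in% c("single", "combinatorial_dual", "unique_dual")) {
    msgs <- c(msgs, "scheme must be single, combinatorial_dual or unique_dual")
  }
  if (length(msgs)) msgs else TRUE
})

#' PoolConfig: a multiplexed single-cell pool
#'
#' Parameters of the cross-sample barcode collision model: number of pooled
#' samples, cells per sample (default 3000, the encapsulation target per
#' sample), size of the cell-barcode space (default 147456 = 384 x 384, the
#' inDrop V2 split-barcode combinations) and the per-cell index-hopping
#' probability (default 0.0485, the documented NovaSeq hopping rate).
#'
#' @slot nSamples,cellsPerSample,barcodeSpace integers.
#' @slot hopRate probability in \[0, 1\].
#' @aliases PoolConfig-class
#' @seealso [pDiscard()], [mcDiscard()]
#' @export
setClass("PoolConfig",
  representation(
    nSamples = "integer", cellsPerSample = "integer",
    barcodeSpace = "integer", hopRate = "numeric"
  )
)

setValidity("PoolConfig", function(object) {
  msgs <- character(0)
  if (object@nSamples < 1L) msgs <- c(msgs, "nSamples must be >= 1")
  if (object@cellsPerSample < 1L) msgs <- c(msgs, "cellsPerSample must be >= 1")
  if (object@barcodeSpace < 1L) msgs <- c(msgs, "barcodeSpace must be >= 1")
  if (object@hopRate < 0 || object@hopRate > 1) {
    msgs <- c(msgs, "hopRate must be in [0, 1]")
  }
  if (length(msgs)) msgs else TRUE
})

#' CollisionEstimate: analytic and Monte-Carlo discard estimates
#'
#' @slot pCollision analytic probability that a cell shares its barcode with
#'   at least one other cell in the pool.
#' @slot pDiscard analytic fraction of cell barcodes discarded (collision or
#'   index hop, combined by inclusion-exclusion).
#' @slot mcMean,mcStderr Monte-Carlo mean discarded fraction and its standard
#'   error over replicate pools (`NA` for purely analytic estimates).
#' @slot nReplicateCells total simulated cells; `seed` the RNG seed used.
#' @slot seed integer RNG seed (`NA` for analytic estimates).
#' @aliases CollisionEstimate
#' @export
setClass("CollisionEstimate",
  representation(
    pCollision = "numeric", pDiscard = "numeric",
    mcMean = "numeric", mcStderr = "numeric",
    nReplicateCells = "numeric", seed = "numeric"
  )
)

setValidity("CollisionEstimate", function(object) {
  p <- c(object@pCollision, object@pDiscard)
  if (any(p < 0 | p > 1)) return("probabilities must be in [0, 1]")
  TRUE
})

#' DemuxReport: demultiplexing tallies
#'
#' Per-sample counts of assigned reads (split into correct and mis-assigned
#' when ground truth is available), totals for hop-filtered and undetermined
#' reads, and derived percentages.
#'
#' @slot perSample data frame with one row per sample: `sampleId`,
#'   `nAssigned`, `nPerfect` (zero-mismatch index reads), `assignedCorrect`,
#'   `assignedWrong` (the latter two `NA` without truth).
#' @slot totals named list: `nReads`, `nAssigned`, `nFilteredHopped`,
#'   `nUndetermined`.
#' @slot percentPerfectIndexReads percent of assigned reads whose observed
#'   indexes match their assigned sample with zero mismatches.
#' @slot misassignmentRate assignedWrong / assigned (`NA` without truth).
#' @slot percentOfTargetDepth observed / target x 100 (`NA` without a target).
#' @aliases DemuxReport
#' @seealso [demultiplex()]
#' @export
setClass("DemuxReport",
  representation(
    perSample = "data.frame", totals = "list",
    percentPerfectIndexReads = "numeric",
    misassignmentRate = "numeric",
    percentOfTargetDepth = "numeric"
  )
)

setValidity("DemuxReport", function(object) {
  t <- object@totals
  need <- c("nReads", "nAssigned", "nFilteredHopped", "nUndetermined")
  if (!all(need %in% names(t))) {
    return(sprintf("totals must contain %s", paste(need, collapse = ", ")))
  }
  if (t$nAssigned + t$nFilteredHopped + t$nUndetermined != t$nReads) {
    return("report categories must sum to the total read count")
  }
  TRUE
})

#' CycleQuality: per-cycle quality summaries of a read
#'
#' @slot meanQ per-cycle mean Phred score.
#' @slot fracAboveThreshold per-cycle fraction of bases with score >=
#'   `threshold` (the Q30 fraction at the default threshold).
#' @slot baseCount per-cycle number of contributing bases (ragged reads
#'   contribute only to the cycles they cover).
#' @slot threshold the quality threshold used.
#' @slot label free-text read label.
#' @aliases CycleQuality
#' @seealso [perCycleQuality()]
#' @export
setClass("CycleQuality",
  representation(
    meanQ = "numeric", fracAboveThreshold = "numeric",
    baseCount = "numeric", threshold = "numeric", label = "character"
  )
)

setValidity("CycleQuality", function(object) {
  n <- length(object@meanQ)
  if (length(object@fracAboveThreshold) != n || length(object@baseCount) != n) {
    return("per-cycle vectors must have equal length")
  }
  f <- object@fracAboveThreshold
  if (any(f < 0 | f > 1, na.rm = TRUE)) return("fractions must be in [0, 1]")
  if (any(object@baseCount < 0)) return("base counts must be nonnegative")
  TRUE
})

#' ExactTestResult: an exact Mann-Whitney test
#'
#' @slot U the Mann-Whitney statistic (number of between-group pairs below;
#'   see [mannWhitneyU()] for the convention used when computed from data).
#' @slot n1,n2 group sizes.
#' @slot pOneSided,pTwoSided exact tail probabilities; the two-sided value is
#'   twice the smaller tail, clamped at 1.
#' @slot method "exact" or "normal_approx".
#' @slot medians group medians (`NA` when the test is built from U alone).
#' @aliases ExactTestResult
#' @seealso [mannWhitneyExact()]
#' @export
setClass("ExactTestResult",
  representation(
    U = "numeric", n1 = "integer", n2 = "integer",
    pOneSided = "numeric", pTwoSided = "numeric",
    method = "character", medians = "numeric"
  )
)

setValidity("ExactTestResult", function(object) {
  msgs <- character(0)
  if (object@U < 0 || object@U > object@n1 * object@n2) {
    msgs <- c(msgs, "U must lie in [0, n1 * n2]")
  }
  for (p in c(object@pOneSided, object@pTwoSided)) {
    if (!is.na(p) && (p <= 0 || p > 1)) msgs <- c(msgs, "p must be in (0, 1]")
  }
  if (length(msgs)) msgs else TRUE
})
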