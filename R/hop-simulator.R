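# Pooled-run simulator with index hopping, FASTQ output, demultiplexing and
# scoring against ground truth.

# n random DNA strings with the given lengths (recycled), built in one pass.
.randomDNA <- function(n, lengths) {
  if (n == 0L) return(character(0))
  lengths <- rep_len(lengths, n)
  codes <- sample(c(65L, 67L, 71L, 84L), sum(lengths), replace = TRUE)
  big <- intToUtf8(codes)
  ends <- cumsum(lengths)
  substring(big, ends - lengths + 1L, ends)
}

# Deterministic mapping from 0-based barcode integers to DNA k-mers
# (base-4 digit encoding); used when cells draw from a finite barcode space.
.encodeBarcode <- function(idx0, width = 8L) {
  stopifnot(all(idx0 >= 0), all(idx0 < 4^width))
  letters4 <- c("A", "C", "G", "T")
  out <- rep("", length(idx0))
  for (i in seq_len(width)) {
    digit <- (idx0 %/% 4^(width - i)) %% 4
    out <- paste0(out, letters4[digit + 1L])
  }
  out
}

.qualityStrings <- function(n, len, model) {
  if (n == 0L) return(character(0))
  len <- rep_len(len, n)
  if (identical(model$type, "constant")) {
    q <- as.integer(model$q)
    return(strrep(intToUtf8(q + 33L), len))
  }
  if (identical(model$type, "profile")) {
    L <- len[1L]
    if (any(len != L)) stop("profile quality model needs uniform read length")
    mu <- rep_len(model$mean, L)
    sdv <- if (is.null(model$sd)) 3 else model$sd
    qm <- matrix(stats::rnorm(n * L, mean = rep(mu, each = n), sd = sdv),
                 nrow = n)
    qm <- pmin(pmax(round(qm), 2L), 41L)
    return(apply(qm, 1L, function(q) intToUtf8(q + 33L)))
  }
  stop("unknown quality model type; use 'constant' or 'profile'")
}

.barcodeReadOf <- function(structure) {
  for (rn in names(structure@readRoles)) {
    if ("cell barcode 1" %in% structure@readRoles[[rn]]$covers) return(rn)
  }
  stop(sprintf("structure '%s' has no cell-barcode read", structure@name))
}

# Default run configurations: V2 on NextSeq reads 100 transcript cycles and a
# 50-cycle barcode+UMI read; TruDrop runs paired 150-cycle reads.
.defaultReadLengths <- function(structure) {
  switch(structure@name,
         INDROP_V2 = c(barcode = 50L, transcript = 100L),
         TRUDROP = c(barcode = 150L, transcript = 150L),
         stop(sprintf("no default read lengths for structure '%s'",
                      structure@name)))
}

#' Simulate a pooled sequencing run with index hopping
#'
#' Generates ground-truth reads for every sample of `sheet` laid out
#' according to `structure`. The barcode read is cell barcode 1 (length
#' drawn from `bc1Lengths`) + the W1 spacer + cell barcode 2 (8 bases) +
#' UMI (6 bases) + poly-T fill; the transcript read is random sequence.
#' Each index side is independently replaced, with probability
#' `hopRate / 2` per side for dual-indexed sheets (total per-read hop
#' probability close to `hopRate` at small rates) or `hopRate` on i7 for
#' single-indexed sheets, by an index drawn uniformly from the other
#' samples' indexes on that side -- the signature of free-adapter mispriming
#' during exclusion-amplification clustering.
#'
#' With `cellsPerSample` set, each sample first receives that many cells
#' whose (barcode 1, barcode 2) pairs are drawn uniformly from a barcode
#' space of `barcodeSpace` combinations (fixed 8-base halves), and reads
#' sample cells uniformly; this is the regime of the cross-sample barcode
#' collision model. Without it, every read draws fresh random barcodes.
#'
#' @param sheet a [SampleSheet-class].
#' @param structure a [LibraryStructure-class] with a cell-barcode read
#'   (`INDROP_V2` or `TRUDROP` preset); a dual sheet requires a dual
#'   structure.
#' @param readsPerSample reads to generate per sample (0 gives an empty
#'   stream).
#' @param hopRate total per-read index hopping probability.
#' @param seed RNG seed; identical seeds and configs give identical output.
#' @param cellsPerSample optional number of cells per sample (see above).
#' @param barcodeSpace size of the (bc1, bc2) barcode space in cell mode.
#' @param bc1Lengths admissible cell-barcode-1 lengths (default 8:11; cell
#'   mode uses fixed 8-base halves).
#' @param qualityModel `list(type = "constant", q = 37)` or
#'   `list(type = "profile", mean = <per-cycle means>, sd = 3)`.
#' @param readLengths named vector `c(barcode = , transcript = )`; defaults
#'   depend on the structure preset.
#' @return data frame with one row per read: `readId`, `trueSample`, `bc1`,
#'   `bc2`, `umi`, `observedI7`, `observedI5`, `hoppedI7`, `hoppedI5`,
#'   `read1Seq`, `read2Seq`, `read1Qual`, `read2Qual` (qualities as
#'   Phred+33 strings).
#' @export
simulatePool <- function(sheet, structure, readsPerSample, hopRate = 0.0485,
                         seed = 1L, cellsPerSample = NULL,
                         barcodeSpace = 147456L, bc1Lengths = 8:11,
                         qualityModel = list(type = "constant", q = 37),
                         readLengths = NULL) {
  stopifnot(is(sheet, "SampleSheet"), is(structure, "LibraryStructure"),
            readsPerSample >= 0L, hopRate >= 0, hopRate <= 1)
  dualSheet <- sheet@scheme != "single"
  dualStructure <- !is.null(structure@readRoles$index2)
  if (dualSheet && !dualStructure) {
    stop("dual-indexed sheet requires a dual-indexed structure")
  }
  barcodeRead <- .barcodeReadOf(structure)
  if (is.null(readLengths)) readLengths <- .defaultReadLengths(structure)
  bcLen <- as.integer(readLengths[["barcode"]])
  txLen <- as.integer(readLengths[["transcript"]])
  if (bcLen < max(bc1Lengths) + nchar(.W1) + 8L + 6L) {
    stop("barcode read too short for barcode 1 + W1 + barcode 2 + UMI")
  }
  e <- sheet@entries
  nSamples <- nrow(e)
  n <- nSamples * as.integer(readsPerSample)

  emptyCols <- data.frame(
    readId = character(0), trueSample = character(0), bc1 = character(0),
    bc2 = character(0), umi = character(0), observedI7 = character(0),
    observedI5 = character(0), hoppedI7 = logical(0), hoppedI5 = logical(0),
    read1Seq = character(0), read2Seq = character(0),
    read1Qual = character(0), read2Qual = character(0),
    stringsAsFactors = FALSE)
  if (n == 0L) return(emptyCols)

  if (hopRate > 0 && nSamples < 2L) {
    stop("hopping requires at least 2 samples (no foreign index to hop to)")
  }

  set.seed(seed)
  sampleIdx <- rep(seq_len(nSamples), each = readsPerSample)

  if (!is.null(cellsPerSample)) {
    stopifnot(cellsPerSample >= 1L)
    # cells first: per-sample barcode draws from the finite space
    cellBc <- lapply(seq_len(nSamples), function(s) {
      idx0 <- sample.int(barcodeSpace, cellsPerSample, replace = TRUE) - 1L
      half <- ceiling(sqrt(barcodeSpace))
      list(bc1 = .encodeBarcode(idx0 %/% half), bc2 = .encodeBarcode(idx0 %% half))
    })
    cellOf <- sample.int(cellsPerSample, n, replace = TRUE)
    bc1 <- vapply(seq_len(n), function(i) cellBc[[sampleIdx[i]]]$bc1[cellOf[i]],
                  character(1))
    bc2 <- vapply(seq_len(n), function(i) cellBc[[sampleIdx[i]]]$bc2[cellOf[i]],
                  character(1))
  } else {
    bc1Lengths <- as.integer(bc1Lengths)
    bc1 <- .randomDNA(n, bc1Lengths[sample.int(length(bc1Lengths), n,
                                               replace = TRUE)])
    bc2 <- .randomDNA(n, 8L)
  }
  umi <- .randomDNA(n, 6L)

  hopTo <- function(true, refs, rate) {
    hopped <- stats::runif(n) < rate
    obs <- true
    if (any(hopped)) {
      obs[hopped] <- vapply(which(hopped), function(i) {
        foreign <- setdiff(unique(refs), refs[sampleIdx[i]])
        sample(foreign, 1L)
      }, character(1))
    }
    list(observed = obs, hopped = hopped)
  }
  i7rate <- if (dualSheet) hopRate / 2 else hopRate
  h7 <- hopTo(e$i7[sampleIdx], e$i7, i7rate)
  if (dualSheet) {
    h5 <- hopTo(e$i5[sampleIdx], e$i5, hopRate / 2)
  } else {
    h5 <- list(observed = rep(NA_character_, n), hopped = rep(FALSE, n))
  }

  barcodeSeq <- paste0(bc1, .W1, bc2, umi)
  barcodeSeq <- paste0(barcodeSeq,
                       strrep("T", bcLen - nchar(barcodeSeq)))
  transcriptSeq <- .randomDNA(n, txLen)
  barcodeQual <- .qualityStrings(n, bcLen, qualityModel)
  transcriptQual <- .qualityStrings(n, txLen, qualityModel)

  if (barcodeRead == "read1") {
    r1s <- barcodeSeq; r1q <- barcodeQual
    r2s <- transcriptSeq; r2q <- transcriptQual
  } else {
    r1s <- transcriptSeq; r1q <- transcriptQual
    r2s <- barcodeSeq; r2q <- barcodeQual
  }

  data.frame(
    readId = sprintf("read%07d", seq_len(n)),
    trueSample = e$sampleId[sampleIdx],
    bc1 = bc1, bc2 = bc2, umi = umi,
    observedI7 = h7$observed, observedI5 = h5$observed,
    hoppedI7 = h7$hopped, hoppedI5 = h5$hopped,
    read1Seq = r1s, read2Seq = r2s,
    read1Qual = r1q, read2Qual = r2q,
    stringsAsFactors = FALSE)
}

#' Write simulated reads as FASTQ
#'
#' Standard 4-line FASTQ, Phred+33. Index reads are emitted as separate
#' I1/I2 files and are also encoded in each header comment as `i7+i5`
#' (`i7` alone for single-indexed runs). Paths ending in `.gz` are
#' gzip-compressed.
#'
#' @param reads a data frame from [simulatePool()].
#' @param r1,r2,i1,i2 output paths; `NULL` entries are skipped.
#' @param indexQuality constant Phred score for index-read bases.
#' @return invisibly, the paths written.
#' @export
writeFastq <- function(reads, r1 = NULL, r2 = NULL, i1 = NULL, i2 = NULL,
                       indexQuality = 37L) {
  single <- all(is.na(reads$observedI5))
  comment <- if (single) reads$observedI7 else
    paste0(reads$observedI7, "+", reads$observedI5)
  headers <- paste0(reads$readId, " ", comment)
  emit <- function(seqs, quals, path) {
    if (is.null(path)) return(invisible(NULL))
    x <- Biostrings::DNAStringSet(seqs)
    names(x) <- headers
    Biostrings::writeXStringSet(
      x, filepath = path, format = "fastq",
      qualities = Biostrings::BStringSet(quals),
      compress = grepl("\\.gz$", path))
    path
  }
  iq <- function(seqs) strrep(intToUtf8(indexQuality + 33L), nchar(seqs))
  written <- c(
    emit(reads$read1Seq, reads$read1Qual, r1),
    emit(reads$read2Seq, reads$read2Qual, r2),
    emit(reads$observedI7, iq(reads$observedI7), i1),
    if (!single) emit(reads$observedI5, iq(reads$observedI5), i2))
  invisible(written)
}

.readFastqIndexes <- function(paths) {
  get <- function(path) {
    if (is.null(path)) return(NULL)
    x <- Biostrings::readDNAStringSet(path, format = "fastq")
    list(id = sub("\\s.*$", "", names(x)), seq = as.character(x))
  }
  r <- lapply(paths, get)
  counts <- vapply(Filter(Negate(is.null), r), function(z) length(z$id),
                   numeric(1))
  if (length(unique(counts)) > 1L) {
    stop("record count mismatch between FASTQ inputs")
  }
  r
}

#' Demultiplex simulated or FASTQ reads
#'
#' Applies [assignReads()] per read and tallies the outcome. Input is
#' either the data frame produced by [simulatePool()] (set
#' `ignoreI5 = TRUE` to demultiplex a dual-indexed simulation in
#' single-index mode, the comparison that exposes hop mis-assignment) or a
#' named list of FASTQ paths `list(i1 = , i2 = , r1 = , r2 = )` (i1
#' required; all provided files must have matching record counts).
#'
#' @param x read data frame or list of FASTQ paths.
#' @param sheet a [SampleSheet-class].
#' @param maxMismatch per-index Hamming tolerance (default 1).
#' @param ignoreI5 drop the i5 index and demultiplex on i7 alone.
#' @param target optional targeted read count; fills the report's
#'   percent-of-target-depth.
#' @return list with `assignments` (per-read data frame: `readId`,
#'   `assigned`, `category`, `perfect`, plus ground-truth columns when
#'   available) and `report` (a [DemuxReport-class]).
#' @export
demultiplex <- function(x, sheet, maxMismatch = 1L, ignoreI5 = FALSE,
                        target = NULL) {
  stopifnot(is(sheet, "SampleSheet"))
  if (is.list(x) && !is.data.frame(x)) {
    fq <- .readFastqIndexes(x[intersect(names(x), c("i1", "i2", "r1", "r2"))])
    if (is.null(fq$i1)) stop("demultiplexing from files requires an i1 input")
    x <- data.frame(readId = fq$i1$id, observedI7 = fq$i1$seq,
                    observedI5 = if (!is.null(fq$i2)) fq$i2$seq else NA_character_,
                    stringsAsFactors = FALSE)
    if (!is.null(fq$i2) && !all(fq$i2$id == fq$i1$id)) {
      stop("read ids differ between I1 and I2 inputs")
    }
  }
  obs5 <- NULL
  if (!ignoreI5 && "observedI5" %in% names(x) && !all(is.na(x$observedI5))) {
    obs5 <- x$observedI5
  }
  res <- assignReads(x$observedI7, obs5, sheet, maxMismatch)
  assignments <- x
  assignments$assigned <- res$assignment
  assignments$category <- res$category
  assignments$perfect <- res$perfect

  ids <- sampleIds(sheet)
  hasTruth <- "trueSample" %in% names(assignments)
  perSample <- do.call(rbind, lapply(ids, function(s) {
    sel <- assignments$assigned == s
    data.frame(
      sampleId = s,
      nAssigned = sum(sel),
      nPerfect = sum(sel & assignments$perfect),
      assignedCorrect = if (hasTruth)
        sum(sel & assignments$trueSample == s) else NA_integer_,
      assignedWrong = if (hasTruth)
        sum(sel & assignments$trueSample != s) else NA_integer_,
      stringsAsFactors = FALSE)
  }))
  totals <- list(
    nReads = nrow(assignments),
    nAssigned = sum(assignments$category == "assigned"),
    nFilteredHopped = sum(assignments$category == "filtered_hopped"),
    nUndetermined = sum(assignments$category == "undetermined"))
  ppi <- if (totals$nAssigned > 0L) {
    100 * sum(perSample$nPerfect) / totals$nAssigned
  } else NA_real_
  mar <- if (hasTruth && totals$nAssigned > 0L) {
    sum(perSample$assignedWrong) / totals$nAssigned
  } else NA_real_
  ptd <- if (!is.null(target)) {
    percentOfTarget(totals$nAssigned, target)
  } else NA_real_
  report <- new("DemuxReport", perSample = perSample, totals = totals,
                percentPerfectIndexReads = ppi, misassignmentRate = mar,
                percentOfTargetDepth = ptd)
  list(assignments = assignments, report = report)
}

#' Score demultiplexing against ground truth
#'
#' @param assignments per-read assignment data frame from [demultiplex()].
#' @param truth optional data frame with `readId`, `trueSample`, `hoppedI7`,
#'   `hoppedI5`; may be omitted when `assignments` already carries those
#'   columns (simulated input). Every assignment read id must be present in
#'   the truth table.
#' @return list with `perSamplePrecision` (named vector: correct / assigned
#'   per sample), `misassignmentRate` (assigned to the wrong sample /
#'   assigned) and `hopCaptureRate` (hopped reads landing in the hop filter
#'   / all hopped reads; `NA` when nothing hopped).
#' @export
scoreDemux <- function(assignments, truth = NULL) {
  if (!is.null(truth)) {
    miss <- setdiff(assignments$readId, truth$readId)
    if (length(miss)) {
      stop(sprintf("read id(s) missing from truth table: %s",
                   paste(utils::head(miss, 3L), collapse = ", ")))
    }
    i <- match(assignments$readId, truth$readId)
    assignments$trueSample <- truth$trueSample[i]
    assignments$hoppedI7 <- truth$hoppedI7[i]
    assignments$hoppedI5 <- truth$hoppedI5[i]
  }
  need <- c("trueSample", "hoppedI7", "hoppedI5")
  if (!all(need %in% names(assignments))) {
    stop("ground truth columns unavailable; pass a truth table")
  }
  assigned <- assignments$category == "assigned"
  hopped <- assignments$hoppedI7 | assignments$hoppedI5
  prec <- vapply(unique(assignments$trueSample), function(s) {
    sel <- assigned & assignments$assigned == s
    if (!any(sel)) return(NA_real_)
    mean(assignments$trueSample[sel] == s)
  }, numeric(1))
  list(
    perSamplePrecision = prec,
    misassignmentRate = if (any(assigned)) {
      mean(assignments$trueSample[assigned] != assignments$assigned[assigned])
    } else NA_real_,
    hopCaptureRate = if (any(hopped)) {
      mean(assignments$category[hopped] == "filtered_hopped")
    } else NA_real_)
}

#' Cross-sample barcode discard for single-indexed pools
#'
#' Emulates the computational countermeasure available to single-indexed
#' pools: a (bc1, bc2) cell barcode observed in the retained (assigned)
#' reads of two or more samples cannot be attributed to a sample and is
#' discarded everywhere. Within-sample collisions and hops that relocate a
#' barcode wholesale are invisible to this rule, which is why it
#' under-recovers compared to the pool-level analytic model ([pDiscard()]).
#'
#' @param assignments data frame with columns `assigned`, `category`,
#'   `bc1`, `bc2` (e.g. [demultiplex()] output on simulated reads).
#' @return list with `nBarcodes` (distinct retained barcodes),
#'   `nDiscarded`, `fraction` (= nDiscarded / nBarcodes) and
#'   `discardedBarcodes` (character vector of `bc1+bc2` keys).
#' @export
singleIndexCollisionLoss <- function(assignments) {
  need <- c("assigned", "category", "bc1", "bc2")
  if (!all(need %in% names(assignments))) {
    stop("assignments must carry assigned, category, bc1, bc2 columns")
  }
  kept <- assignments[assignments$category == "assigned", , drop = FALSE]
  if (nrow(kept) == 0L) {
    return(list(nBarcodes = 0L, nDiscarded = 0L, fraction = NA_real_,
                discardedBarcodes = character(0)))
  }
  key <- paste0(kept$bc1, "+", kept$bc2)
  pairs <- unique(data.frame(key = key, sample = kept$assigned,
                             stringsAsFactors = FALSE))
  nSamplesPerBc <- table(pairs$key)
  discarded <- names(nSamplesPerBc)[nSamplesPerBc >= 2L]
  list(nBarcodes = length(nSamplesPerBc),
       nDiscarded = length(discarded),
       fraction = length(discarded) / length(nSamplesPerBc),
       discardedBarcodes = discarded)
}
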