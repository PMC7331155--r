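# Accessor generics. Slot access from user code is discouraged; these are the
# supported surface.

#' @rdname LibraryStructure-class
#' @param object,x an object of the documented class.
#' @export
setGeneric("structureName", function(object) standardGeneric("structureName"))

#' @rdname LibraryStructure-class
#' @param side `"p5_side"` or `"p7_side"`.
#' @export
setGeneric("structureSegments",
           function(object, side) standardGeneric("structureSegments"))

#' @rdname LibraryStructure-class
#' @export
setGeneric("readRoles", function(object) standardGeneric("readRoles"))

#' @rdname PrimerSet-class
#' @export
setGeneric("primerSequences",
           function(object) standardGeneric("primerSequences"))

#' @rdname SampleSheet-class
#' @export
setGeneric("sampleIds", function(object) standardGeneric("sampleIds"))

#' @rdname SampleSheet-class
#' @export
setGeneric("i7Indexes", function(object) standardGeneric("i7Indexes"))

#' @rdname SampleSheet-class
#' @export
setGeneric("i5Indexes", function(object) standardGeneric("i5Indexes"))

#' @rdname SampleSheet-class
#' @export
setGeneric("indexScheme", function(object) standardGeneric("indexScheme"))

#' @rdname SampleSheet-class
#' @export
setGeneric("sheetEntries", function(object) standardGeneric("sheetEntries"))

#' @rdname DemuxReport-class
#' @export
setGeneric("perSampleCounts",
           function(object) standardGeneric("perSampleCounts"))

#' @rdname DemuxReport-class
#' @export
setGeneric("reportTotals", function(object) standardGeneric("reportTotals"))

#' @rdname DemuxReport-class
#' @export
setGeneric("percentPerfectIndexReads",
           function(object) standardGeneric("percentPerfectIndexReads"))

#' @rdname DemuxReport-class
#' @export
setGeneric("misassignmentRate",
           function(object) standardGeneric("misassignmentRate"))

#' @rdname ExactTestResult-class
#' @export
setGeneric("pValue", function(object, ...) standardGeneric("pValue"))

setMethod("structureName", "LibraryStructure", function(object) object@name)

setMethod("structureSegments", "LibraryStructure", function(object, side) {
  side <- .matchSide(side)
  slot(object, side)
})

setMethod("readRoles", "LibraryStructure", function(object) object@readRoles)

setMethod("primerSequences", "PrimerSet", function(object) {
  c(read1 = object@read1, read2 = object@read2,
    index1 = object@index1, index2 = object@index2)
})

setMethod("sampleIds", "SampleSheet", function(object) object@entries$sampleId)
setMethod("i7Indexes", "SampleSheet", function(object) object@entries$i7)
setMethod("i5Indexes", "SampleSheet", function(object) object@entries$i5)
setMethod("indexScheme", "SampleSheet", function(object) object@scheme)
setMethod("sheetEntries", "SampleSheet", function(object) object@entries)

setMethod("perSampleCounts", "DemuxReport", function(object) object@perSample)
setMethod("reportTotals", "DemuxReport", function(object) object@totals)
setMethod("percentPerfectIndexReads", "DemuxReport",
          function(object) object@percentPerfectIndexReads)
setMethod("misassignmentRate", "DemuxReport",
          function(object) object@misassignmentRate)

#' @describeIn ExactTestResult-class two-sided (default) or one-sided p.
#' @param sided `"two"` or `"one"`.
#' @param ... passed on to methods.
setMethod("pValue", "ExactTestResult", function(object, sided = c("two", "one")) {
  sided <- match.arg(sided)
  if (sided == "two") object@pTwoSided else object@pOneSided
})

setMethod("show", "LibraryStructure", function(object) {
  cat(sprintf("LibraryStructure '%s'\n", object@name))
  cat("  p5 side: ", renderTemplate(object, "p5_side"), "\n", sep = "")
  cat("  p7 side: ", renderTemplate(object, "p7_side"), "\n", sep = "")
  cat("  reads:   ", paste(names(object@readRoles), collapse = ", "), "\n",
      sep = "")
})

setMethod("show", "PrimerSet", function(object) {
  cat(sprintf("PrimerSet derived from '%s'\n", object@structure))
  p <- primerSequences(object)
  for (nm in names(p)) {
    if (!is.na(p[[nm]])) cat(sprintf("  %-6s 5'-%s-3'\n", nm, p[[nm]]))
  }
})

setMethod("show", "SampleSheet", function(object) {
  cat(sprintf("SampleSheet: %d sample(s), scheme '%s'\n",
              nrow(object@entries), object@scheme))
  print(object@entries, row.names = FALSE)
})

setMethod("show", "PoolConfig", function(object) {
  cat(sprintf(
    "PoolConfig: %d sample(s) x %d cells, barcode space %d, hop rate %.4f\n",
    object@nSamples, object@cellsPerSample, object@barcodeSpace,
    object@hopRate))
})

setMethod("show", "CollisionEstimate", function(object) {
  cat("CollisionEstimate\n")
  cat(sprintf("  analytic: P(collision) = %.6f, P(discard) = %.6f\n",
              object@pCollision, object@pDiscard))
  if (!is.na(object@mcMean)) {
    cat(sprintf("  Monte Carlo: %.6f +/- %.6f (SE; %g cells, seed %g)\n",
                object@mcMean, object@mcStderr, object@nReplicateCells,
                object@seed))
  }
})

setMethod("show", "DemuxReport", function(object) {
  t <- object@totals
  cat(sprintf(
    "DemuxReport: %d reads (%d assigned, %d hop-filtered, %d undetermined)\n",
    t$nReads, t$nAssigned, t$nFilteredHopped, t$nUndetermined))
  cat(sprintf("  percent perfect index reads: %.2f%%\n",
              object@percentPerfectIndexReads))
  if (!is.na(object@misassignmentRate)) {
    cat(sprintf("  misassignment rate: %.5f\n", object@misassignmentRate))
  }
  print(object@perSample, row.names = FALSE)
})

setMethod("show", "CycleQuality", function(object) {
  cat(sprintf(
    "CycleQuality%s: %d cycles, overall mean Q %.2f, Q>=%d fraction %.3f\n",
    if (nzchar(object@label)) paste0(" [", object@label, "]") else "",
    length(object@meanQ),
    stats::weighted.mean(object@meanQ, object@baseCount),
    as.integer(object@threshold),
    stats::weighted.mean(object@fracAboveThreshold, object@baseCount)))
})

setMethod("show", "ExactTestResult", function(object) {
  cat(sprintf("Mann-Whitney test (%s)\n", object@method))
  cat(sprintf("  U = %g, n1 = %d, n2 = %d\n", object@U, object@n1, object@n2))
  if (!all(is.na(object@medians))) {
    cat(sprintf("  medians: %.4g vs %.4g\n",
                object@medians[1], object@medians[2]))
  }
  cat(sprintf("  one-sided p = %.4g, two-sided p = %.4g\n",
              object@pOneSided, object@pTwoSided))
})
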