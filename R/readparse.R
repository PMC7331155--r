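# inDrop barcode-read parsing and per-structure cycle region maps.

#' Parse inDrop barcode reads
#'
#' Locates the fixed 22-base W1 spacer by scanning the offsets allowed for
#' the variable-length cell barcode 1 (default 8-11 bases) with at most
#' `maxW1Mismatch` Hamming mismatches (no indels; the spacer tolerance must
#' stay well below the whitelist distance to avoid mis-anchoring). The
#' prefix before W1 is barcode 1, the next 8 bases barcode 2, the following
#' 6 the UMI; the fraction of trailing bases that are T (the poly-T capture
#' stretch read through) is reported as `polyTFraction`. Reads where W1 is
#' not found at any admissible offset give an invalid record with a
#' diagnostic, never an error.
#'
#' @param seqs character vector of barcode-read sequences.
#' @param w1 the W1 spacer sequence.
#' @param maxW1Mismatch Hamming tolerance for the spacer (default 2).
#' @param bc1Lengths admissible barcode-1 lengths / W1 offsets.
#' @param whitelistBc1,whitelistBc2 optional barcode whitelists; when given,
#'   both barcodes must match (exactly, or within `whitelistMismatch`) for
#'   `valid = TRUE`.
#' @param whitelistMismatch allowed whitelist mismatches (default 0, exact).
#' @return data frame with columns `bc1`, `bc2`, `umi`, `bc1Length`,
#'   `w1Mismatches`, `polyTFraction`, `valid`, `reason` (`NA` when valid).
#' @examples
#' parseBarcodeReads(paste0("ACGTACGT", "GAGTGATTGCTTGTGACGCCTT",
#'                          "CCCCCCCC", "AATTGG", "TTTTTT"))
#' @export
parseBarcodeReads <- function(seqs, w1 = "GAGTGATTGCTTGTGACGCCTT",
                              maxW1Mismatch = 2L, bc1Lengths = 8:11,
                              whitelistBc1 = NULL, whitelistBc2 = NULL,
                              whitelistMismatch = 0L) {
  seqs <- toupper(seqs)
  n <- length(seqs)
  wlen <- nchar(w1)
  minUse <- min(bc1Lengths) + wlen + 8L + 6L
  out <- data.frame(
    bc1 = NA_character_, bc2 = NA_character_, umi = NA_character_,
    bc1Length = NA_integer_, w1Mismatches = NA_integer_,
    polyTFraction = NA_real_, valid = FALSE, reason = NA_character_,
    stringsAsFactors = FALSE)[rep(1L, n), , drop = FALSE]
  rownames(out) <- NULL
  if (n == 0L) return(out)

  short <- nchar(seqs) < minUse
  out$reason[short] <- "too_short"

  # per admissible offset, Hamming distance of the candidate spacer window
  offs <- sort(as.integer(bc1Lengths))
  dm <- matrix(NA_integer_, nrow = n, ncol = length(offs))
  for (j in seq_along(offs)) {
    window <- substr(seqs, offs[j] + 1L, offs[j] + wlen)
    ok <- !short & nchar(window) == wlen
    d <- rep(NA_integer_, n)
    if (any(ok)) d[ok] <- .hammingToRef(window[ok], w1)
    dm[, j] <- d
  }
  best <- apply(dm, 1L, function(d) {
    if (all(is.na(d))) return(NA_integer_)
    which.min(d)  # ties -> smallest offset
  })
  found <- !is.na(best)
  bi <- cbind(seq_len(n), ifelse(found, best, 1L))
  bestMism <- ifelse(found, dm[bi], NA_integer_)
  bestOff <- ifelse(found, offs[best], NA_integer_)

  out$w1Mismatches <- bestMism
  hit <- found & bestMism <= maxW1Mismatch
  out$reason[found & !hit] <- "w1_not_found"

  if (any(hit)) {
    o <- bestOff[hit]
    s <- seqs[hit]
    out$bc1[hit] <- substr(s, 1L, o)
    out$bc1Length[hit] <- o
    out$bc2[hit] <- substr(s, o + wlen + 1L, o + wlen + 8L)
    out$umi[hit] <- substr(s, o + wlen + 9L, o + wlen + 14L)
    tail <- substr(s, o + wlen + 15L, nchar(s))
    tlen <- nchar(tail)
    nT <- tlen - nchar(gsub("T", "", tail))
    out$polyTFraction[hit] <- ifelse(tlen > 0L, nT / tlen, NA_real_)
    out$valid[hit] <- TRUE
  }

  matchWhitelist <- function(bc, wl) {
    u <- unique(bc[!is.na(bc)])
    ok <- vapply(u, function(b) {
      if (b %in% wl) return(TRUE)
      if (whitelistMismatch > 0L) {
        same <- wl[nchar(wl) == nchar(b)]
        length(same) > 0L && any(.hammingToRef(same, b) <= whitelistMismatch)
      } else FALSE
    }, logical(1))
    ok[match(bc, u)]
  }
  if (!is.null(whitelistBc1)) {
    bad <- out$valid & !matchWhitelist(out$bc1, toupper(whitelistBc1))
    out$valid[bad] <- FALSE
    out$reason[bad] <- "bc1_not_in_whitelist"
  }
  if (!is.null(whitelistBc2)) {
    bad <- out$valid & !matchWhitelist(out$bc2, toupper(whitelistBc2))
    out$valid[bad] <- FALSE
    out$reason[bad] <- "bc2_not_in_whitelist"
  }
  out
}

#' @rdname parseBarcodeReads
#' @param seq a single barcode-read sequence.
#' @param ... passed on to `parseBarcodeReads`.
#' @return `parseBarcodeRead` returns a one-row list.
#' @export
parseBarcodeRead <- function(seq, ...) {
  as.list(parseBarcodeReads(seq, ...)[1L, ])
}

# Published run layouts, 0-based half-open cycle intervals.
.regionPresets <- function() {
  list(
    # NextSeq custom run: 100 transcript cycles, 6-cycle i7 read, 50-cycle
    # barcode + UMI read (its last ~6 cycles read into the poly-A tail
    # because barcode 1 varies in length).
    V2_NEXTSEQ = list(
      regions = data.frame(
        read = c("transcript_read", "index1_read", "barcode_read"),
        region = c("transcript", "index1", "barcode_umi"),
        start = c(0L, 0L, 0L), end = c(100L, 6L, 50L),
        stringsAsFactors = FALSE),
      qcRegions = data.frame(
        read = c("transcript_read", "barcode_read"),
        region = c("transcript", "barcode_umi"),
        start = c(0L, 0L), end = c(100L, 50L), stringsAsFactors = FALSE)),
    # Paired 150-cycle run, 8-cycle index reads. QC follows the published
    # intervals: barcode cycles 1-11 and 31-50 (the intervening cycles are
    # attributed to the W1 spacer), transcript scored on its first 100
    # cycles only for comparability across platforms.
    TRUDROP = list(
      regions = data.frame(
        read = c("barcode_read", "barcode_read", "barcode_read",
                 "barcode_read", "index1_read", "index2_read",
                 "transcript_read"),
        region = c("barcode1", "w1", "barcode2_umi", "polyT",
                   "index1", "index2", "transcript"),
        start = c(0L, 11L, 30L, 50L, 0L, 0L, 0L),
        end = c(11L, 30L, 50L, 150L, 8L, 8L, 150L),
        stringsAsFactors = FALSE),
      qcRegions = data.frame(
        read = c("barcode_read", "barcode_read", "transcript_read"),
        region = c("barcode1", "barcode2_umi", "transcript"),
        start = c(0L, 30L, 0L), end = c(11L, 50L, 100L),
        stringsAsFactors = FALSE))
  )
}

#' Cycle region map for a run preset
#'
#' Returns the published cycle layouts as 0-based half-open intervals, one
#' row per region, grouped by read. The `qcRegions` attribute carries the
#' intervals over which region-weighted quality is scored (see
#' [regionMeanQuality()]); for the TruDrop preset these are the published
#' barcode QC cycles (1-11 and 31-50, 1-based) and the first 100 transcript
#' cycles.
#'
#' @param preset `"V2_NEXTSEQ"` or `"TRUDROP"`.
#' @return data frame (`read`, `region`, `start`, `end`) with attribute
#'   `qcRegions`.
#' @export
regionMap <- function(preset) {
  presets <- .regionPresets()
  preset <- toupper(preset)
  if (!preset %in% names(presets)) {
    stop(sprintf("unknown preset '%s'; valid presets: %s", preset,
                 paste(names(presets), collapse = ", ")))
  }
  p <- presets[[preset]]
  out <- p$regions
  attr(out, "qcRegions") <- p$qcRegions
  out
}
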