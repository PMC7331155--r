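# Sample-index validation and hop-aware read assignment.

#' Construct a sample sheet
#'
#' @param sampleId character vector of unique sample names, or a data frame
#'   with columns `sampleId` (or `sample_id`), `i7` and optionally `i5`.
#' @param i7 i7 index sequences (P7 side).
#' @param i5 i5 index sequences (P5 side), or `NULL` for a single-indexed
#'   sheet. Sequences are upper-cased on ingest.
#' @return a [SampleSheet-class] with the indexing scheme classified and
#'   cached (see [classifyScheme()]).
#' @examples
#' SampleSheet(c("Mouse4", "Mouse5"),
#'             i7 = c("CCGCGGTT", "TTATAACC"),
#'             i5 = c("AGCGCTAG", "GATATCGA"))
#' @export
SampleSheet <- function(sampleId, i7 = NULL, i5 = NULL) {
  if (is.data.frame(sampleId)) {
    df <- sampleId
    names(df)[names(df) == "sample_id"] <- "sampleId"
    sampleId <- df$sampleId
    i7 <- df$i7
    i5 <- if ("i5" %in% names(df)) df$i5 else NULL
  }
  if (is.null(i5)) i5 <- rep(NA_character_, length(sampleId))
  i5 <- as.character(i5)
  i5[!is.na(i5) & !nzchar(trimws(i5))] <- NA_character_
  entries <- data.frame(
    sampleId = as.character(sampleId),
    i7 = toupper(trimws(as.character(i7))),
    i5 = toupper(trimws(i5)),
    stringsAsFactors = FALSE
  )
  new("SampleSheet", entries = entries, scheme = .classifyEntries(entries))
}

.classifyEntries <- function(entries) {
  hasI5 <- !is.na(entries$i5)
  if (any(hasI5) && !all(hasI5)) {
    stop("mixed presence/absence of i5 across entries")
  }
  if (!any(hasI5)) return("single")
  if (!anyDuplicated(entries$i7) && !anyDuplicated(entries$i5)) {
    "unique_dual"
  } else {
    "combinatorial_dual"
  }
}

#' Read / write a sample sheet as CSV or TSV
#'
#' Expects a header `sample_id,i7,i5` (the `i5` column is optional); the
#' delimiter is inferred from the file contents.
#'
#' @param path file path.
#' @param sheet a [SampleSheet-class] (for writing).
#' @return a [SampleSheet-class] / `path` invisibly.
#' @export
readSampleSheet <- function(path) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  SampleSheet(df)
}

#' @rdname readSampleSheet
#' @export
writeSampleSheet <- function(sheet, path) {
  stopifnot(is(sheet, "SampleSheet"))
  e <- sheet@entries
  out <- data.frame(sample_id = e$sampleId, i7 = e$i7, i5 = e$i5)
  if (indexScheme(sheet) == "single") out$i5 <- NULL
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Levenshtein edit distance between two sequences
#'
#' Minimum number of insertions, deletions and substitutions transforming
#' `a` into `b` (the criterion under which published index sets guarantee
#' that a single base error cannot turn one index into another: pairwise
#' distance of at least 2 on each side).
#'
#' @param a,b non-empty DNA sequences.
#' @return integer edit distance.
#' @examples
#' levenshteinDistance("CCGCGGTT", "TTATAACC")  # 8
#' @export
levenshteinDistance <- function(a, b) {
  stopifnot(is.character(a), is.character(b), nzchar(a), nzchar(b))
  as.integer(utils::adist(toupper(a), toupper(b)))
}

#' Classify the indexing scheme of a sample sheet
#'
#' `single` when no sample carries an i5; `unique_dual` when no index is
#' reused on either side (every hopped read then shows an unanticipated
#' index combination and can be filtered); `combinatorial_dual` when some
#' index is repeated on one side (some hops are undetectable).
#'
#' @param sheet a [SampleSheet-class] or a data frame accepted by
#'   [SampleSheet()].
#' @return one of `"single"`, `"combinatorial_dual"`, `"unique_dual"`.
#' @export
classifyScheme <- function(sheet) {
  if (!is(sheet, "SampleSheet")) sheet <- SampleSheet(sheet)
  sheet@scheme
}

#' Validate a sample-index set
#'
#' Reports every pair of i7 indexes (and, for dual sheets, every pair of i5
#' indexes) whose Levenshtein distance is below `minDistance`, any mixing of
#' index lengths within a side, and a scheme warning when the sheet is not
#' unique-dual. The two sides are checked independently, never across sides.
#'
#' @param sheet a [SampleSheet-class].
#' @param minDistance minimum tolerated pairwise edit distance (default 2).
#' @return data frame of violations with columns `type` (`"distance"`,
#'   `"length"` or `"scheme"`), `side`, `sampleA`, `sampleB`, `indexA`,
#'   `indexB`, `distance`, `message`; zero rows means the set passes.
#' @export
validateIndexSet <- function(sheet, minDistance = 2L) {
  stopifnot(is(sheet, "SampleSheet"), minDistance >= 0L)
  e <- sheet@entries
  emptyRow <- function() data.frame(
    type = character(0), side = character(0),
    sampleA = character(0), sampleB = character(0),
    indexA = character(0), indexB = character(0),
    distance = integer(0), message = character(0),
    stringsAsFactors = FALSE)
  out <- emptyRow()
  sides <- if (sheet@scheme == "single") "i7" else c("i7", "i5")
  for (side in sides) {
    idx <- e[[side]]
    if (length(unique(nchar(idx))) > 1L) {
      out <- rbind(out, data.frame(
        type = "length", side = side, sampleA = NA, sampleB = NA,
        indexA = NA, indexB = NA, distance = NA,
        message = sprintf("mixed %s index lengths within the sheet", side)))
    }
    if (nrow(e) < 2L) next
    d <- utils::adist(idx)
    for (i in seq_len(nrow(e) - 1L)) {
      for (j in seq((i + 1L), nrow(e))) {
        if (d[i, j] < minDistance) {
          out <- rbind(out, data.frame(
            type = "distance", side = side,
            sampleA = e$sampleId[i], sampleB = e$sampleId[j],
            indexA = idx[i], indexB = idx[j],
            distance = as.integer(d[i, j]),
            message = sprintf("%s pair below minimum edit distance %d",
                              side, minDistance)))
        }
      }
    }
  }
  if (sheet@scheme != "unique_dual" && nrow(e) > 1L) {
    out <- rbind(out, data.frame(
      type = "scheme", side = NA, sampleA = NA, sampleB = NA,
      indexA = NA, indexB = NA, distance = NA,
      message = sprintf(
        "scheme is '%s', not unique_dual: some index hops cannot be filtered",
        sheet@scheme)))
  }
  rownames(out) <- NULL
  out
}

#' Anticipated index combinations of a dual-indexed sheet
#'
#' @param sheet a dual-indexed [SampleSheet-class].
#' @return data frame with columns `i7`, `i5`, `sampleId`, one row per
#'   sample; the lookup structure the demultiplexer uses to separate
#'   anticipated combinations from hopped ones.
#' @export
expectedCombinations <- function(sheet) {
  stopifnot(is(sheet, "SampleSheet"))
  if (sheet@scheme == "single") {
    stop("expectedCombinations requires a dual-indexed sheet")
  }
  e <- sheet@entries
  key <- paste(e$i7, e$i5, sep = "+")
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1L]
    stop(sprintf("duplicate index combination across samples: %s", dup))
  }
  data.frame(i7 = e$i7, i5 = e$i5, sampleId = e$sampleId,
             stringsAsFactors = FALSE)
}

# Hamming distances between a character vector of equal-length sequences and
# one reference sequence.
.hammingToRef <- function(x, ref) {
  n <- nchar(ref)
  d <- integer(length(x))
  for (i in seq_len(n)) {
    d <- d + (substr(x, i, i) != substr(ref, i, i))
  }
  d
}

# Match each observed index to the unique sheet index within maxMismatch on
# its side. Returns the matched index sequence, NA when unmatched or
# ambiguous (>= 2 distinct sheet indexes within tolerance).
.matchSide2 <- function(observed, refs, maxMismatch) {
  lens <- unique(nchar(refs))
  if (length(lens) != 1L) {
    stop("sheet mixes index lengths on one side; cannot Hamming-match")
  }
  uo <- unique(observed)
  if (any(nchar(uo) != lens)) {
    stop("observed indexes must have the same length as the sheet indexes")
  }
  urefs <- unique(refs)
  dmat <- vapply(urefs, function(r) .hammingToRef(uo, r),
                 integer(length(uo)))
  dmat <- matrix(dmat, nrow = length(uo))
  hit <- apply(dmat, 1L, function(d) {
    ok <- which(d <= maxMismatch)
    if (length(ok) == 1L) ok else NA_integer_
  })
  matched <- ifelse(is.na(hit), NA_character_, urefs[hit])
  mism <- dmat[cbind(seq_along(uo), ifelse(is.na(hit), 1L, hit))]
  mism[is.na(hit)] <- NA_integer_
  i <- match(observed, uo)
  list(index = matched[i], mismatches = mism[i])
}

#' Assign reads to samples from observed index reads
#'
#' Each observed index is matched to the unique sheet index within
#' `maxMismatch` Hamming mismatches on its own side. For dual-indexed
#' sheets, a read whose two matched indexes form an anticipated combination
#' is assigned to that sample; a read whose indexes both match sheet indexes
#' but in an unanticipated combination is an index-hopped read and is
#' filtered (`"filtered_hopped"`); any unmatched or ambiguous side gives
#' `"undetermined"`. Single-indexed sheets use only i7 and can never return
#' `"filtered_hopped"` -- hops are invisible to them.
#'
#' @param i7 observed i7 sequences (character vector).
#' @param i5 observed i5 sequences, or `NULL` to demultiplex in single-index
#'   mode (also used to ignore i5 deliberately).
#' @param sheet a [SampleSheet-class].
#' @param maxMismatch per-index Hamming tolerance (default 1).
#' @return list with `assignment` (sample id, `"filtered_hopped"` or
#'   `"undetermined"`), `perfect` (logical: zero mismatches on every index
#'   used) and `category` (`"assigned"`, `"filtered_hopped"`,
#'   `"undetermined"`).
#' @examples
#' sheet <- SampleSheet(c("Mouse4", "Mouse5"),
#'                      i7 = c("CCGCGGTT", "TTATAACC"),
#'                      i5 = c("AGCGCTAG", "GATATCGA"))
#' assignReads("CCGCGGTT", "GATATCGA", sheet)$assignment  # filtered_hopped
#' @export
assignReads <- function(i7, i5 = NULL, sheet, maxMismatch = 1L) {
  stopifnot(is(sheet, "SampleSheet"))
  if (maxMismatch < 0L) stop("maxMismatch must be >= 0")
  e <- sheet@entries
  i7 <- toupper(i7)
  m7 <- .matchSide2(i7, e$i7, maxMismatch)
  useI5 <- !is.null(i5) && sheet@scheme != "single"
  if (useI5) {
    i5 <- toupper(i5)
    if (length(i5) != length(i7)) stop("i7 and i5 must have equal length")
    m5 <- .matchSide2(i5, e$i5, maxMismatch)
    comb <- expectedCombinations(sheet)
    key <- paste(m7$index, m5$index, sep = "+")
    hit <- match(key, paste(comb$i7, comb$i5, sep = "+"))
    bothMatched <- !is.na(m7$index) & !is.na(m5$index)
    assignment <- ifelse(!bothMatched, "undetermined",
                         ifelse(is.na(hit), "filtered_hopped",
                                comb$sampleId[ifelse(is.na(hit), 1L, hit)]))
    perfect <- bothMatched & !is.na(hit) &
      m7$mismatches == 0L & m5$mismatches == 0L
  } else {
    if (anyDuplicated(e$i7)) {
      stop("single-index assignment needs distinct i7 indexes")
    }
    hit <- match(m7$index, e$i7)
    assignment <- ifelse(is.na(hit), "undetermined",
                         e$sampleId[ifelse(is.na(hit), 1L, hit)])
    perfect <- !is.na(hit) & m7$mismatches == 0L
  }
  category <- ifelse(assignment == "undetermined", "undetermined",
                     ifelse(assignment == "filtered_hopped",
                            "filtered_hopped", "assigned"))
  list(assignment = assignment, perfect = perfect, category = category)
}

#' @rdname assignReads
#' @param observedI7,observedI5 a single observed index pair.
#' @return `assignRead` returns the assignment label alone.
#' @export
assignRead <- function(observedI7, observedI5 = NULL, sheet,
                       maxMismatch = 1L) {
  assignReads(observedI7, observedI5, sheet, maxMismatch)$assignment
}
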