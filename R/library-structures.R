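# Library-structure presets and template/primer operations.
#
# The three presets encode the printed adapter/template sequences of the
# standard Illumina TruSeq library, the single-indexed inDrop V2 library and
# the dual-indexed TruSeq-inDrop (TruDrop) library. Fixed segments are stored
# verbatim; sample indexes, cell barcodes, the UMI and the insert are
# placeholders with a length range (index 6-10 bases, cell barcode 1 8-11,
# cell barcode 2 8, UMI 6).

.matchSide <- function(side) {
  side <- match.arg(tolower(side), c("p5_side", "p7_side", "p5side", "p7side"))
  if (side %in% c("p5_side", "p5side")) "p5Side" else "p7Side"
}

#' Reverse complement of a DNA sequence
#'
#' @param seq a single DNA string over A/C/G/T/N (case-insensitive).
#' @return the reverse complement (upper case); N maps to N.
#' @examples
#' revComp("AGAT")            # "ATCT"
#' revComp("GCTCTTCCGATCT")   # "AGATCGGAAGAGC"
#' @export
revComp <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L, !is.na(seq))
  seq <- toupper(seq)
  bad <- regexpr("[^ACGTN]", seq)
  if (bad > 0L) {
    stop(sprintf("non-IUPAC character '%s' at position %d",
                 substr(seq, bad, bad), bad))
  }
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

.segment <- function(label, role, sequence = NA_character_,
                     minLen = NA_real_, maxLen = NA_real_) {
  if (!is.na(sequence)) {
    sequence <- toupper(sequence)
    minLen <- maxLen <- nchar(sequence)
  }
  data.frame(label = label, role = role, sequence = sequence,
             minLen = minLen, maxLen = maxLen, stringsAsFactors = FALSE)
}

.W1 <- "GAGTGATTGCTTGTGACGCCTT"
.POLYT <- strrep("T", 19L)
.P5_ADAPTER <- "AATGATACGGCGACCACCGAGATCTACAC"
.P7_ADAPTER <- "CAAGCAGAAGACGGCATACGAGAT"
.R1_SITE <- "ACACTCTTTCCCTACACGACGCTCTTCCGATCT"
.R2_SITE <- "GTGACTGGAGTTCAGACGTGTGCTCTTCCGATCT"
.V2_TRUNCATED_R1_SITE <- "CTCTTTCCCTACACGACGCTCTTCCGATCT"
.V2_OBSOLETE_SITE <- "GGTCTCGGCATTCCTGCTGAACCGCTCTTCCGATCT"

.barcodeSegments <- function() {
  rbind(
    .segment("cell barcode 1", "cell_barcode", minLen = 8, maxLen = 11),
    .segment("w1", "spacer", .W1),
    .segment("cell barcode 2", "cell_barcode", minLen = 8, maxLen = 8),
    .segment("UMI", "umi", minLen = 6, maxLen = 6),
    .segment("polyT", "polyT", .POLYT)
  )
}

# The insert of the V2/TruDrop transcript templates is printed as the
# 6-base random hexamer NNNNNN; its true length is unbounded.
.insertSegment <- function(printed = TRUE) {
  data.frame(label = "insert", role = "insert",
             sequence = if (printed) "NNNNNN" else NA_character_,
             minLen = 6, maxLen = Inf, stringsAsFactors = FALSE)
}

.buildStructures <- function() {
  truseq <- new("LibraryStructure",
    name = "TRUSEQ",
    p5Side = rbind(
      .segment("p5_adapter", "flowcell_adapter", .P5_ADAPTER),
      .segment("i5", "sample_index", minLen = 6, maxLen = 10),
      .segment("r1_site", "priming_site", .R1_SITE),
      .insertSegment(printed = FALSE)
    ),
    p7Side = rbind(
      .segment("p7_adapter", "flowcell_adapter", .P7_ADAPTER),
      .segment("i7", "sample_index", minLen = 6, maxLen = 10),
      .segment("r2_site", "priming_site", .R2_SITE)
    ),
    readRoles = list(
      read1 = list(covers = "insert", primingSite = "r1_site"),
      read2 = list(covers = "insert", primingSite = "r2_site"),
      index1 = list(covers = "i7", primingSite = "r2_site"),
      index2 = list(covers = "i5", primingSite = "r1_site")
    )
  )

  indropV2 <- new("LibraryStructure",
    name = "INDROP_V2",
    # transcript side: obsolete R2-derived priming site, added via the
    # random hexamer during the second RT
    p5Side = rbind(
      .segment("p5_adapter", "flowcell_adapter", .P5_ADAPTER),
      .segment("obsolete_r2_site", "priming_site", .V2_OBSOLETE_SITE),
      .insertSegment()
    ),
    # barcode + UMI side: truncated R1 priming site built into the bead oligo
    p7Side = rbind(
      .segment("p7_adapter", "flowcell_adapter", .P7_ADAPTER),
      .segment("i7", "sample_index", minLen = 6, maxLen = 10),
      .segment("truncated_r1_site", "priming_site", .V2_TRUNCATED_R1_SITE),
      .barcodeSegments()
    ),
    # reads are flipped relative to TruSeq: the insert is read first
    readRoles = list(
      read1 = list(covers = "insert", primingSite = "obsolete_r2_site"),
      read2 = list(covers = c("cell barcode 1", "w1", "cell barcode 2",
                              "UMI", "polyT"),
                   primingSite = "truncated_r1_site"),
      index1 = list(covers = "i7", primingSite = "truncated_r1_site")
    )
  )

  trudrop <- new("LibraryStructure",
    name = "TRUDROP",
    # barcode + UMI side moved to P5 with the standard TruSeq R1 site, so
    # the higher-quality read 1 carries the cell barcodes and UMI
    p5Side = rbind(
      .segment("p5_adapter", "flowcell_adapter", .P5_ADAPTER),
      .segment("i5", "sample_index", minLen = 6, maxLen = 10),
      .segment("r1_site", "priming_site", .R1_SITE),
      .barcodeSegments()
    ),
    p7Side = rbind(
      .segment("p7_adapter", "flowcell_adapter", .P7_ADAPTER),
      .segment("i7", "sample_index", minLen = 6, maxLen = 10),
      .segment("r2_site", "priming_site", .R2_SITE),
      .insertSegment()
    ),
    readRoles = list(
      read1 = list(covers = c("cell barcode 1", "w1", "cell barcode 2",
                              "UMI", "polyT"),
                   primingSite = "r1_site"),
      read2 = list(covers = "insert", primingSite = "r2_site"),
      index1 = list(covers = "i7", primingSite = "r2_site"),
      index2 = list(covers = "i5", primingSite = "r1_site")
    )
  )

  list(TRUSEQ = truseq, INDROP_V2 = indropV2, TRUDROP = trudrop)
}

.structures <- NULL

#' Built-in library structure presets
#'
#' @param name one of `"TRUSEQ"`, `"INDROP_V2"`, `"TRUDROP"`.
#' @return a [LibraryStructure-class] whose rendered templates reproduce the
#'   published adapter/template strings.
#' @examples
#' getStructure("TRUDROP")
#' @export
getStructure <- function(name) {
  if (is.null(.structures)) {
    utils::assignInMyNamespace(".structures", .buildStructures())
  }
  name <- toupper(name)
  if (!name %in% names(.structures)) {
    stop(sprintf("unknown structure '%s'; valid names: %s", name,
                 paste(names(.structures), collapse = ", ")))
  }
  .structures[[name]]
}

#' Render one side of a library structure as a template string
#'
#' Fixed segments are emitted verbatim; placeholders as bracketed tokens
#' (e.g. `[i7]`, `[cell barcode 1]`). `placeholderStyle = "spaced"` puts a
#' space on either side of each token, which is the dialect the templates
#' are conventionally printed in; `"bracket"` (default) emits a compact
#' string. An insert placeholder with a printed random-hexamer sequence
#' renders as `NNNNNN`; an unprinted insert (TruSeq adapters are given
#' without their insert) renders as nothing.
#'
#' @param structure a [LibraryStructure-class].
#' @param side `"p5_side"` or `"p7_side"`.
#' @param placeholderStyle `"bracket"` or `"spaced"`.
#' @return a single template string.
#' @examples
#' renderTemplate(getStructure("INDROP_V2"), "p5_side")
#' @export
renderTemplate <- function(structure, side,
                           placeholderStyle = c("bracket", "spaced")) {
  stopifnot(is(structure, "LibraryStructure"))
  placeholderStyle <- match.arg(placeholderStyle)
  seg <- slot(structure, .matchSide(side))
  if (nrow(seg) == 0L) return("")
  piece <- ifelse(!is.na(seg$sequence), seg$sequence,
                  paste0("[", seg$label, "]"))
  piece <- piece[!(seg$role == "insert" & is.na(seg$sequence))]
  if (placeholderStyle == "spaced") {
    tok <- grepl("^\\[", piece)
    piece[tok] <- paste0(" ", piece[tok], " ")
    out <- gsub("  ", " ", paste(piece, collapse = ""))
    trimws(out)
  } else {
    paste(piece, collapse = "")
  }
}

.segmentByLabel <- function(structure, label) {
  seg <- rbind(structure@p5Side, structure@p7Side)
  hit <- seg[seg$label == label, , drop = FALSE]
  if (nrow(hit) == 0L) {
    stop(sprintf("structure '%s' has no segment '%s'", structure@name, label))
  }
  hit[1L, ]
}

#' Derive sequencing primers from a library structure
#'
#' Read primers equal their priming-site sequences. Index-read primers are
#' the reverse complement of the priming site immediately flanking the index
#' on the template (the standard Illumina convention: the index read primes
#' off the opposite strand, so the primer's 5' end is the reverse complement
#' of the priming site's 3' end).
#'
#' @param structure a [LibraryStructure-class] with read roles.
#' @return a [PrimerSet-class]; roles the structure does not declare (e.g.
#'   index2 of the single-indexed V2 design) are `NA`.
#' @examples
#' deriveSequencingPrimers(getStructure("INDROP_V2"))
#' @export
deriveSequencingPrimers <- function(structure) {
  stopifnot(is(structure, "LibraryStructure"))
  roles <- structure@readRoles
  if (length(roles) == 0L) stop("structure declares no read roles")
  primer <- function(readName) {
    if (is.null(roles[[readName]])) return(NA_character_)
    site <- .segmentByLabel(structure, roles[[readName]]$primingSite)
    if (is.na(site$sequence)) {
      stop(sprintf("priming site '%s' of read '%s' has no fixed sequence",
                   site$label, readName))
    }
    if (grepl("^index", readName)) revComp(site$sequence) else site$sequence
  }
  new("PrimerSet",
      read1 = primer("read1"), read2 = primer("read2"),
      index1 = primer("index1"), index2 = primer("index2"),
      structure = structure@name)
}

#' Longest shared 5' prefix of two sequences
#'
#' Length of the longest exact common prefix, the quantity that exposes the
#' mispriming hazard between the V2 custom index primer and the standard
#' Illumina index primer (13 shared 5' bases).
#'
#' @param a,b non-empty sequences.
#' @return integer prefix length.
#' @export
longestSharedPrefix <- function(a, b) {
  stopifnot(is.character(a), is.character(b),
            length(a) == 1L, length(b) == 1L, nzchar(a), nzchar(b))
  n <- min(nchar(a), nchar(b))
  ca <- substring(a, seq_len(n), seq_len(n))
  cb <- substring(b, seq_len(n), seq_len(n))
  mism <- which(ca != cb)
  if (length(mism) == 0L) n else mism[1L] - 1L
}

#' Cross-structure mispriming hazard report
#'
#' For each read role declared by both structures, compares the two derived
#' primers by [longestSharedPrefix()] and flags pairs whose shared 5' region
#' is at least `threshold` bases. Primers for the same read are delivered to
#' the flow cell during the same sequencing step, so a long shared 5' region
#' between them lets one library's clusters misprime with the other
#' library's primer. The default threshold of 13 is the observed hazard
#' length between the inDrop V2 custom i7 index primer and the standard
#' Illumina index primer.
#'
#' @param a,b two [LibraryStructure-class] objects (may be identical).
#' @param threshold flag pairs sharing at least this many 5' bases.
#' @return data frame with columns `role`, `primerA`, `primerB`,
#'   `sharedPrefix`, `identical`, `flagged`.
#' @examples
#' misprimingReport(getStructure("INDROP_V2"), getStructure("TRUSEQ"))
#' @export
misprimingReport <- function(a, b, threshold = 13L) {
  stopifnot(is(a, "LibraryStructure"), is(b, "LibraryStructure"),
            threshold >= 1L)
  pa <- primerSequences(deriveSequencingPrimers(a))
  pb <- primerSequences(deriveSequencingPrimers(b))
  roles <- intersect(names(pa)[!is.na(pa)], names(pb)[!is.na(pb)])
  rows <- lapply(roles, function(r) {
    shared <- longestSharedPrefix(pa[[r]], pb[[r]])
    data.frame(role = r, primerA = pa[[r]], primerB = pb[[r]],
               sharedPrefix = shared,
               identical = identical(pa[[r]], pb[[r]]),
               flagged = shared >= threshold,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "structures") <- c(a@name, b@name)
  attr(out, "threshold") <- threshold
  out
}

#' Export / import a library structure as a plain config document
#'
#' One YAML record per segment (`label`, `role`, `sequence` or `null`,
#' `minLen`, `maxLen`) per side, plus the read-role map.
#'
#' @param structure a [LibraryStructure-class].
#' @param path file to write / read.
#' @return `readStructureConfig` returns the reconstructed
#'   [LibraryStructure-class]; `writeStructureConfig` returns `path`
#'   invisibly.
#' @export
writeStructureConfig <- function(structure, path) {
  stopifnot(is(structure, "LibraryStructure"))
  sideRecords <- function(seg) {
    lapply(seq_len(nrow(seg)), function(i) {
      s <- seg[i, ]
      list(label = s$label, role = s$role,
           sequence = if (is.na(s$sequence)) NULL else s$sequence,
           minLen = if (is.finite(s$minLen)) s$minLen else "inf",
           maxLen = if (is.finite(s$maxLen)) s$maxLen else "inf")
    })
  }
  doc <- list(
    name = structure@name,
    p5_side = sideRecords(structure@p5Side),
    p7_side = sideRecords(structure@p7Side),
    read_roles = structure@readRoles
  )
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' @rdname writeStructureConfig
#' @export
readStructureConfig <- function(path) {
  doc <- yaml::read_yaml(path)
  fromRecords <- function(records) {
    do.call(rbind, lapply(records, function(s) {
      num <- function(v) if (identical(v, "inf")) Inf else as.numeric(v)
      .segment(s$label, s$role,
               sequence = if (is.null(s$sequence)) NA_character_ else s$sequence,
               minLen = num(s$minLen), maxLen = num(s$maxLen))
    }))
  }
  new("LibraryStructure",
      name = doc$name,
      p5Side = fromRecords(doc$p5_side),
      p7Side = fromRecords(doc$p7_side),
      readRoles = doc$read_roles)
}
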