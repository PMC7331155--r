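test_that("revComp follows complement rules and rejects bad input", {
  expect_identical(revComp("AGAT"), "ATCT")
  # the shared 13-mer underlying the mispriming hazard
  expect_identical(revComp("GCTCTTCCGATCT"), "AGATCGGAAGAGC")
  expect_identical(revComp("acgtn"), "NACGT")
  expect_error(revComp("ACGXT"), "position 4")
})

test_that("revComp is an involution and preserves length", {
  set.seed(11)
  for (len in c(1, 5, 22, 80)) {
    s <- randomDNAString(5, len)
    for (x in s) {
      expect_identical(revComp(revComp(x)), x)
      expect_identical(nchar(revComp(x)), nchar(x))
    }
  }
})

printedTemplates <- list(
  TRUSEQ = c(
    p7_side = "CAAGCAGAAGACGGCATACGAGAT[i7]GTGACTGGAGTTCAGACGTGTGCTCTTCCGATCT",
    p5_side = "AATGATACGGCGACCACCGAGATCTACAC[i5]ACACTCTTTCCCTACACGACGCTCTTCCGATCT"),
  INDROP_V2 = c(
    p7_side = paste0("CAAGCAGAAGACGGCATACGAGAT [i7] ",
                     "CTCTTTCCCTACACGACGCTCTTCCGATCT [cell barcode 1] ",
                     "GAGTGATTGCTTGTGACGCCTT [Cell barcode 2] [UMI] ",
                     "TTTTTTTTTTTTTTTTTTT"),
    p5_side = paste0("AATGATACGGCGACCACCGAGATCTACAC",
                     "GGTCTCGGCATTCCTGCTGAACCGCTCTTCCGATCTNNNNNN")),
  TRUDROP = c(
    p7_side = paste0("CAAGCAGAAGACGGCATACGAGAT [i7] ",
                     "GTGACTGGAGTTCAGACGTGTGCTCTTCCGATCTNNNNNN"),
    p5_side = paste0("AATGATACGGCGACCACCGAGATCTACAC [i5] ",
                     "ACACTCTTTCCCTACACGACGCTCTTCCGATCT [cell barcode 1] ",
                     "GAGTGATTGCTTGTGACGCCTT [cell barcode 2] [UMI] ",
                     "TTTTTTTTTTTTTTTTTTT"))
)

test_that("presets reproduce the printed templates after whitespace normalization", {
  for (nm in names(printedTemplates)) {
    st <- getStructure(nm)
    for (side in names(printedTemplates[[nm]])) {
      expect_identical(
        normalizeTemplate(renderTemplate(st, side, "spaced")),
        normalizeTemplate(printedTemplates[[nm]][[side]]),
        label = paste(nm, side))
      # both placeholder dialects agree after normalization
      expect_identical(
        normalizeTemplate(renderTemplate(st, side, "bracket")),
        normalizeTemplate(renderTemplate(st, side, "spaced")))
    }
  }
  expect_error(getStructure("NOVASEQ"), "valid names")
})

test_that("structure invariants hold: poly-T, index2 presence, read1 swap", {
  v2 <- getStructure("INDROP_V2")
  td <- getStructure("TRUDROP")
  segs <- structureSegments(td, "p5_side")
  expect_identical(segs$sequence[segs$label == "polyT"], strrep("T", 19))
  expect_null(readRoles(v2)$index2)         # V2 is single-indexed
  expect_true("cell barcode 1" %in% readRoles(td)$read1$covers)
  expect_identical(readRoles(td)$read2$covers, "insert")
})

test_that("derived primers follow the index-read reverse-complement rule", {
  pv2 <- primerSequences(deriveSequencingPrimers(getStructure("INDROP_V2")))
  pts <- primerSequences(deriveSequencingPrimers(getStructure("TRUSEQ")))
  ptd <- primerSequences(deriveSequencingPrimers(getStructure("TRUDROP")))
  expect_identical(pv2[["index1"]], "AGATCGGAAGAGCGTCGTGTAGGGAAAGAG")
  expect_identical(pts[["index1"]], "AGATCGGAAGAGCACACGTCTGAACTCCAGTCAC")
  expect_true(is.na(pv2[["index2"]]))
  # TruDrop adopts the standard TruSeq priming sites
  expect_identical(ptd[["read1"]], pts[["read1"]])
  expect_identical(ptd[["read2"]], pts[["read2"]])
  # and both differ from the V2 custom sites
  expect_false(ptd[["read1"]] %in% c(pv2[["read1"]], pv2[["read2"]]))
  expect_false(ptd[["read2"]] %in% c(pv2[["read1"]], pv2[["read2"]]))
})

test_that("longestSharedPrefix is exact, symmetric and bounded", {
  a <- revComp("CTCTTTCCCTACACGACGCTCTTCCGATCT")       # V2 index primer
  b <- revComp("GTGACTGGAGTTCAGACGTGTGCTCTTCCGATCT")   # TruSeq index primer
  expect_identical(longestSharedPrefix(a, b), 13L)
  expect_identical(longestSharedPrefix("AAAA", "CCCC"), 0L)
  s <- "GATTACA"
  expect_identical(longestSharedPrefix(s, s), nchar(s))
  set.seed(5)
  for (i in 1:20) {
    x <- randomDNAString(1, sample(3:15, 1))
    y <- randomDNAString(1, sample(3:15, 1))
    expect_identical(longestSharedPrefix(x, y), longestSharedPrefix(y, x))
    expect_lte(longestSharedPrefix(x, y), min(nchar(x), nchar(y)))
  }
})

test_that("mispriming report flags the V2 / TruSeq index-read hazard", {
  v2 <- getStructure("INDROP_V2")
  ts <- getStructure("TRUSEQ")
  td <- getStructure("TRUDROP")
  rep1 <- misprimingReport(v2, ts, threshold = 13)
  idx <- rep1[rep1$role == "index1", ]
  expect_identical(idx$sharedPrefix, 13L)
  expect_true(idx$flagged)
  expect_false(any(rep1$flagged[rep1$role != "index1"]))

  self <- misprimingReport(ts, ts, threshold = 13)
  expect_true(all(self$identical))
  expect_identical(self$sharedPrefix, nchar(self$primerA))
  expect_true(all(self$flagged))

  # TruDrop uses the standard primers: only exact-identical pairs flag
  rep2 <- misprimingReport(td, ts, threshold = 13)
  expect_true(all(rep2$flagged == rep2$identical))
})

test_that("structure config round-trips through YAML", {
  td <- getStructure("TRUDROP")
  path <- tempfile(fileext = ".yaml")
  writeStructureConfig(td, path)
  back <- readStructureConfig(path)
  expect_identical(structureName(back), "TRUDROP")
  for (side in c("p5_side", "p7_side")) {
    expect_identical(renderTemplate(back, side), renderTemplate(td, side))
  }
  expect_identical(
    primerSequences(deriveSequencingPrimers(back)),
    primerSequences(deriveSequencingPrimers(td)))
})
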