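test_that("a hop-free pool demultiplexes losslessly", {
  sheet <- truDropSheet()
  reads <- simulatePool(sheet, getStructure("TRUDROP"), 500, hopRate = 0,
                        seed = 1)
  expect_identical(nrow(reads), 1000L)
  expect_false(any(reads$hoppedI7 | reads$hoppedI5))
  e <- sheetEntries(sheet)
  expect_identical(reads$observedI7, e$i7[match(reads$trueSample, e$sampleId)])

  d <- demultiplex(reads, sheet)
  t <- reportTotals(d$report)
  expect_identical(t$nAssigned, t$nReads)
  expect_identical(t$nFilteredHopped, 0L)
  expect_identical(t$nUndetermined, 0L)
  expect_identical(misassignmentRate(d$report), 0)
  expect_identical(percentPerfectIndexReads(d$report), 100)

  sc <- scoreDemux(d$assignments)
  expect_identical(sc$misassignmentRate, 0)
  expect_true(all(sc$perSamplePrecision == 1))
})

test_that("hop injection matches the configured rate and layout invariants", {
  sheet <- truDropSheet()
  h <- 0.0485
  n <- 4e4
  reads <- simulatePool(sheet, getStructure("TRUDROP"), n / 2, hopRate = h,
                        seed = 7)
  frac <- mean(reads$hoppedI7 | reads$hoppedI5)
  expected <- 1 - (1 - h / 2)^2   # per-side independence
  se <- sqrt(expected * (1 - expected) / n)
  expect_lt(abs(frac - expected), 3 * se)

  # observed differs from the true sample's index iff the hop flag is set
  e <- sheetEntries(sheet)
  own7 <- e$i7[match(reads$trueSample, e$sampleId)]
  own5 <- e$i5[match(reads$trueSample, e$sampleId)]
  expect_identical(reads$observedI7 != own7, reads$hoppedI7)
  expect_identical(reads$observedI5 != own5, reads$hoppedI5)

  # read 1 carries barcode 1 + W1 + barcode 2 + UMI + poly-T fill
  expect_identical(substr(reads$read1Seq, 1, nchar(reads$bc1)), reads$bc1)
  w1 <- substr(reads$read1Seq, nchar(reads$bc1) + 1, nchar(reads$bc1) + 22)
  expect_true(all(w1 == "GAGTGATTGCTTGTGACGCCTT"))
  expect_true(all(nchar(reads$read1Seq) == 150L))
})

test_that("degenerate simulator inputs behave as documented", {
  sheet <- truDropSheet()
  empty <- simulatePool(sheet, getStructure("TRUDROP"), 0, hopRate = 0.1,
                        seed = 1)
  expect_identical(nrow(empty), 0L)
  one <- SampleSheet("only", i7 = "CCGCGGTT", i5 = "AGCGCTAG")
  expect_error(
    simulatePool(one, getStructure("TRUDROP"), 10, hopRate = 0.1, seed = 1),
    "foreign index")
  expect_error(
    simulatePool(sheet, getStructure("TRUSEQ"), 10, hopRate = 0, seed = 1),
    "cell-barcode read")
})

test_that("FASTQ output round-trips and is deterministic under a seed", {
  sheet <- truDropSheet()
  reads <- simulatePool(sheet, getStructure("TRUDROP"), 40, hopRate = 0.2,
                        seed = 13)
  dir <- tempfile(); dir.create(dir)
  paths <- file.path(dir, c("r1.fastq", "r2.fastq", "i1.fastq", "i2.fastq"))
  writeFastq(reads, r1 = paths[1], r2 = paths[2], i1 = paths[3],
             i2 = paths[4])

  lines <- readLines(paths[1])
  expect_identical(length(lines), 4L * nrow(reads))
  expect_identical(substr(lines[1], 1, 1), "@")
  expect_identical(substr(lines[3], 1, 1), "+")

  # Biostrings warns about dropped metadata columns on FASTQ ingest
  x <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(paths[1]))
  expect_identical(as.character(unname(x)), reads$read1Seq)
  expect_identical(as.character(unname(Biostrings::quality(x))),
                   reads$read1Qual)
  # header comment carries the observed i7+i5
  expect_identical(sub("^\\S+\\s", "", names(x)),
                   paste0(reads$observedI7, "+", reads$observedI5))

  i1 <- Biostrings::readDNAStringSet(paths[3], format = "fastq")
  expect_identical(as.character(unname(i1)), reads$observedI7)

  # Phred+33 encoding at the extremes
  fake <- reads[1, ]
  fake$read1Seq <- "ACGT"
  fake$read1Qual <- intToUtf8(c(0, 40, 20, 33) + 33)
  writeFastq(fake, r1 = file.path(dir, "enc.fastq"))
  enc <- readLines(file.path(dir, "enc.fastq"))
  expect_identical(substr(enc[4], 1, 2), "!I")

  # byte-identical regeneration under the same seed
  reads2 <- simulatePool(sheet, getStructure("TRUDROP"), 40, hopRate = 0.2,
                         seed = 13)
  writeFastq(reads2, r1 = file.path(dir, "r1b.fastq"))
  expect_identical(readLines(file.path(dir, "r1b.fastq")), lines)

  d <- demultiplex(list(i1 = paths[3], i2 = paths[4]), sheet)
  expect_identical(d$assignments$readId, reads$readId)
  truthOnly <- reads[, c("readId", "trueSample", "hoppedI7", "hoppedI5")]
  sc <- scoreDemux(d$assignments, truth = truthOnly)
  expect_true(is.numeric(sc$misassignmentRate))
  expect_error(scoreDemux(d$assignments, truth = truthOnly[-1, ]),
               "missing from truth")
})

test_that("unique-dual filtering is sound; single-index mode mis-assigns", {
  sheet <- truDropSheet()
  reads <- simulatePool(sheet, getStructure("TRUDROP"), 5000,
                        hopRate = 0.0485, seed = 23)
  dual <- demultiplex(reads, sheet)
  singleSide <- xor(reads$hoppedI7, reads$hoppedI5)
  expect_true(any(singleSide))
  expect_identical(
    sum(singleSide & dual$assignments$category == "assigned"), 0L)
  # double hops to the other sample's pair are undetectable -> assigned_wrong
  wrong <- dual$assignments$category == "assigned" &
    dual$assignments$assigned != dual$assignments$trueSample
  expect_true(all(reads$hoppedI7[wrong] & reads$hoppedI5[wrong]))

  single <- demultiplex(reads, sheet, ignoreI5 = TRUE)
  expect_identical(reportTotals(single$report)$nFilteredHopped, 0L)
  expect_gt(sum(perSampleCounts(single$report)$assignedWrong), 0L)
})

test_that("hop capture rate is 1 for single-side hops", {
  # constructed assignments: every hopped read has exactly one hopped side
  a <- data.frame(
    readId = sprintf("r%d", 1:6),
    trueSample = c("A", "A", "B", "B", "A", "B"),
    hoppedI7 = c(FALSE, TRUE, FALSE, FALSE, FALSE, TRUE),
    hoppedI5 = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE),
    assigned = c("A", "filtered_hopped", "filtered_hopped", "B", "A",
                 "filtered_hopped"),
    category = c("assigned", "filtered_hopped", "filtered_hopped",
                 "assigned", "assigned", "filtered_hopped"),
    stringsAsFactors = FALSE)
  sc <- scoreDemux(a)
  expect_identical(sc$hopCaptureRate, 1)
  expect_identical(sc$misassignmentRate, 0)
})

test_that("cross-sample barcode discard finds planted and random collisions", {
  # disjoint barcodes, nothing hopped -> nothing discarded
  a <- data.frame(
    assigned = c("A", "A", "B"), category = "assigned",
    bc1 = c("AAAAAAAA", "CCCCCCCC", "GGGGGGGG"), bc2 = "TTTTTTTT",
    stringsAsFactors = FALSE)
  res <- singleIndexCollisionLoss(a)
  expect_identical(res$nDiscarded, 0L)

  # plant one shared barcode
  b <- rbind(a, data.frame(assigned = "B", category = "assigned",
                           bc1 = "AAAAAAAA", bc2 = "TTTTTTTT"))
  res2 <- singleIndexCollisionLoss(b)
  expect_identical(res2$discardedBarcodes, "AAAAAAAA+TTTTTTTT")
  expect_equal(res2$fraction, 1 / 3)

  # cell mode: the discarded set must equal the intersection of the two
  # samples' observed barcode sets (independent tally via intersect), and
  # with these parameters the expected overlap (~ n^2 / N scaled by cell
  # coverage) is comfortably nonzero
  sheet <- v2SingleSheetUniform()
  nCells <- 500L; space <- 5000L
  reads <- simulatePool(sheet, getStructure("INDROP_V2"), 3L * nCells,
                        hopRate = 0, seed = 31, cellsPerSample = nCells,
                        barcodeSpace = space)
  d <- demultiplex(reads, sheet)
  res3 <- singleIndexCollisionLoss(d$assignments)
  key <- paste0(reads$bc1, "+", reads$bc2)
  shared <- intersect(key[reads$trueSample == "Mouse2"],
                      key[reads$trueSample == "Mouse3"])
  expect_identical(sort(res3$discardedBarcodes), sort(shared))
  expect_gt(res3$nDiscarded, 0L)
})
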