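test_that("perCycleQuality summarizes constant and mixed qualities", {
  q40 <- perCycleQuality(matrix(40L, nrow = 10, ncol = 5))
  expect_true(all(q40@meanQ == 40))
  expect_true(all(q40@fracAboveThreshold == 1))
  expect_identical(q40@baseCount, rep(10, 5))

  mix <- perCycleQuality(rbind(matrix(20L, 5, 3), matrix(40L, 5, 3)))
  expect_true(all(mix@meanQ == 30))
  expect_true(all(mix@fracAboveThreshold == 0.5))

  # ragged reads contribute only to the cycles they cover
  rag <- perCycleQuality(list(c(30L, 36L), c(30L, 36L), 30L))
  expect_identical(rag@baseCount, c(3, 2))
  expect_identical(rag@meanQ, c(30, 36))
})

test_that("simulated per-cycle decay profiles are recovered", {
  profile <- seq(38, 28, length.out = 50)
  reads <- simulatePool(
    truDropSheet(), getStructure("TRUDROP"), 1500, hopRate = 0, seed = 41,
    qualityModel = list(type = "profile", mean = profile, sd = 3),
    readLengths = c(barcode = 50L, transcript = 50L))
  cq <- perCycleQuality(reads$read1Qual)
  se <- 3 / sqrt(3000)
  # clamping to [2, 41] and rounding leave the interior means unbiased
  expect_true(all(abs(cq@meanQ - profile) < 3 * se + 0.3))
})

test_that("region-weighted quality weights cycles by base counts", {
  uni <- perCycleQuality(matrix(35L, 20, 10))
  rm <- regionMeanQuality(uni, data.frame(region = c("a", "b"),
                                          start = c(0, 4), end = c(4, 10)))
  expect_identical(unname(rm), c(35, 35))

  # counts (100, 50) with means (30, 36): (100*30 + 50*36) / 150 = 32
  rag <- perCycleQuality(c(rep(list(c(30L, 36L)), 50), rep(list(30L), 50)))
  got <- regionMeanQuality(rag, data.frame(region = "r", start = 0, end = 2))
  expect_identical(unname(got), 32)

  # a 150-cycle read scored on its first 100 cycles only
  q <- c(rep(38L, 100), rep(20L, 50))
  cq <- perCycleQuality(matrix(rep(q, each = 5), nrow = 5))
  qc <- regionMeanQuality(cq, data.frame(region = "transcript",
                                         start = 0, end = 100))
  expect_identical(unname(qc), 38)

  expect_error(
    regionMeanQuality(uni, data.frame(region = "x", start = 3, end = 3)),
    "empty region")
  expect_error(
    regionMeanQuality(uni, data.frame(region = "x", start = 0, end = 99)),
    "outside")
})

test_that("qToError follows the Phred definition", {
  expect_identical(qToError(30), 1e-3)
  expect_identical(qToError(0), 1)
  expect_identical(qToError(10), 0.1)
  q <- seq(0, 41, by = 0.5)
  expect_true(all(diff(qToError(q)) < 0))
  expect_error(qToError(-1), ">= 0")
})

test_that("errorFoldChange reproduces the published fold decreases", {
  expect_identical(round(errorFoldChange(8.803e-4, 4.917e-4), 1), 1.8)
  expect_identical(round(errorFoldChange(8.455e-4, 4.908e-4), 1), 1.7)
  expect_identical(errorFoldChange(0.01, 0.01), 1)
  expect_error(errorFoldChange(0.1, 0), "> 0")
})

test_that("exact Mann-Whitney p-values match brute-force enumeration", {
  for (n1 in 1:5) for (n2 in 1:5) {
    counts <- bruteForceMWCounts(n1, n2)
    total <- choose(n1 + n2, n1)
    expect_identical(sum(counts), total)
    for (U in 0:(n1 * n2)) {
      u <- min(U, n1 * n2 - U)
      pb <- sum(counts[seq_len(u + 1)]) / total
      res <- mannWhitneyExact(U, n1, n2)
      expect_identical(pValue(res, "one"), pb)
      expect_identical(pValue(res), min(1, 2 * pb))
    }
  }
})

test_that("exact Mann-Whitney agrees with the R reference distribution", {
  # dwilcox is the independent oracle for the published group sizes
  for (case in list(c(0, 26, 11), c(11, 21, 11), c(25, 21, 11),
                    c(49, 21, 11))) {
    U <- case[1]; n1 <- case[2]; n2 <- case[3]
    u <- min(U, n1 * n2 - U)
    expect_equal(pValue(mannWhitneyExact(U, n1, n2), "one"),
                 sum(stats::dwilcox(0:u, n1, n2)), tolerance = 1e-12)
  }
  expect_error(mannWhitneyExact(300, 26, 11), "lie in")
  expect_error(mannWhitneyExact(1.5, 4, 4), "integer")
})

test_that("normal approximation converges to the exact tail", {
  ex <- pValue(mannWhitneyExact(130, 20, 20))
  ap <- pValue(mannWhitneyExact(130, 20, 20, method = "normal_approx"))
  expect_lt(abs(ap - ex) / ex, 0.05)
})

test_that("mannWhitneyU computes the statistic from raw samples", {
  x <- c(35.57, 35.53, 35.36, 35.40)  # all above every y
  y <- c(33.06, 33.12, 32.03)
  res <- mannWhitneyU(x, y)
  expect_identical(res@U, 0)
  expect_identical(pValue(res),
                   pValue(mannWhitneyExact(0, 4, 3)))
  expect_identical(res@medians,
                   c(stats::median(x), stats::median(y)))

  set.seed(61)
  a <- stats::rnorm(9); b <- stats::rnorm(7) + 0.8
  got <- mannWhitneyU(a, b)
  ref <- stats::wilcox.test(a, b, exact = TRUE)
  expect_equal(pValue(got), ref$p.value, tolerance = 1e-12)

  expect_error(mannWhitneyU(c(1, 2, 2), c(3, 4)), "ties")
})

test_that("percentOfTarget rounds half-up to one decimal", {
  expect_identical(percentOfTarget(10985817, 50e6), 22.0)
  expect_identical(percentOfTarget(44554464, 50e6), 89.1)
  expect_identical(percentOfTarget(5, 5), 100)
  expect_identical(percentOfTarget(1005, 10000), 10.1)  # half-up at .05
  expect_error(percentOfTarget(10, 0), "> 0")
})
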