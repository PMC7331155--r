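# Sequencing-quality statistics: per-cycle summaries, region-weighted
# quality, error probabilities and the exact Mann-Whitney test.

.qualitiesToList <- function(input) {
  if (is.character(input) && length(input) == 1L && file.exists(input)) {
    x <- Biostrings::readQualityScaledDNAStringSet(input)
    q <- as(Biostrings::quality(x), "IntegerList")
    return(as.list(q))
  }
  if (is.character(input)) {
    # Phred+33 quality strings
    return(lapply(input, function(s) utf8ToInt(s) - 33L))
  }
  if (is.matrix(input)) return(asplit(input, 1L))
  if (is.list(input)) return(input)
  stop("input must be a FASTQ path, quality strings, a matrix or a list")
}

#' Per-cycle quality summary
#'
#' Mean Phred score and fraction of bases at or above `qThreshold` for each
#' cycle, over all reads; ragged reads contribute only to the cycles they
#' cover. The threshold-30 fraction per cycle is the quantity plotted in
#' base-calling accuracy (Q30) plots.
#'
#' @param input a FASTQ path (Phred+33), a character vector of Phred+33
#'   quality strings, a reads-by-cycles integer matrix, or a list of
#'   per-read integer quality vectors.
#' @param qThreshold quality threshold (default 30).
#' @param label optional read label.
#' @return a [CycleQuality-class].
#' @export
perCycleQuality <- function(input, qThreshold = 30L, label = "") {
  ql <- .qualitiesToList(input)
  if (length(ql) == 0L) stop("no reads in input")
  maxLen <- max(lengths(ql))
  sums <- numeric(maxLen)
  above <- numeric(maxLen)
  counts <- numeric(maxLen)
  for (q in ql) {
    idx <- seq_along(q)
    sums[idx] <- sums[idx] + q
    above[idx] <- above[idx] + (q >= qThreshold)
    counts[idx] <- counts[idx] + 1
  }
  new("CycleQuality",
      meanQ = sums / counts,
      fracAboveThreshold = above / counts,
      baseCount = counts,
      threshold = as.numeric(qThreshold),
      label = label)
}

#' Region-weighted mean quality
#'
#' Weighted average of the per-cycle mean scores over each region, with
#' weights proportional to the per-cycle base counts inside the region (for
#' uniform-length reads this reduces to a plain mean). This is the
#' region-level summary used to compare transcript and barcode + UMI
#' quality between runs.
#'
#' @param cq a [CycleQuality-class].
#' @param regions data frame with columns `region`, `start`, `end`
#'   (0-based half-open cycle intervals), e.g. a subset of [regionMap()].
#' @return named numeric vector, one weighted mean Q per region.
#' @export
regionMeanQuality <- function(cq, regions) {
  stopifnot(is(cq, "CycleQuality"),
            all(c("region", "start", "end") %in% names(regions)))
  L <- length(cq@meanQ)
  out <- vapply(seq_len(nrow(regions)), function(i) {
    s <- regions$start[i]
    e <- regions$end[i]
    if (e <= s) stop(sprintf("empty region '%s'", regions$region[i]))
    if (s < 0L || e > L) {
      stop(sprintf("region '%s' [%d,%d) outside the %d-cycle read",
                   regions$region[i], s, e, L))
    }
    cyc <- (s + 1L):e
    stats::weighted.mean(cq@meanQ[cyc], cq@baseCount[cyc])
  }, numeric(1))
  names(out) <- regions$region
  out
}

#' Phred score to error probability
#'
#' `p = 10^(-Q/10)`: Q30 corresponds to an error probability of 0.001.
#'
#' @param Q quality score(s), >= 0.
#' @return error probability, strictly decreasing in Q.
#' @export
qToError <- function(Q) {
  if (any(Q < 0)) stop("Q must be >= 0")
  10^(-Q / 10)
}

#' Fold change between two error probabilities
#'
#' @param pBefore,pAfter base-calling error probabilities; `pAfter` > 0.
#' @return `pBefore / pAfter`, the fold decrease in error rate.
#' @examples
#' errorFoldChange(8.803e-4, 4.917e-4)  # ~1.79, reported as a 1.8-fold drop
#' @export
errorFoldChange <- function(pBefore, pAfter) {
  if (any(pAfter <= 0)) stop("pAfter must be > 0")
  pBefore / pAfter
}

# Exact null counts of the Mann-Whitney statistic: N(u; m, n) arrangements
# of m + n group labels give statistic u, via the standard recurrence
#   N(u; m, n) = N(u - n; m - 1, n) + N(u; m, n - 1).
# Equivalently N(u; m, n) is the number of partitions of u into at most
# min(m, n) parts each of size <= max(m, n). Counts stay below 2^53 for the
# group sizes of interest, so double arithmetic is exact.
.mwCounts <- function(n1, n2) {
  row <- rep(list(1), n2 + 1L)  # m = 0
  if (n1 == 0L) return(row[[n2 + 1L]])
  for (m in seq_len(n1)) {
    newrow <- vector("list", n2 + 1L)
    newrow[[1L]] <- 1  # n = 0
    for (n in seq_len(n2)) {
      len <- m * n + 1L
      av <- c(numeric(n), row[[n + 1L]])            # N(u - n; m - 1, n)
      bv <- c(newrow[[n]], numeric(len - (m * (n - 1L) + 1L)))
      newrow[[n + 1L]] <- av + bv
    }
    row <- newrow
  }
  row[[n2 + 1L]]
}

#' Exact Mann-Whitney test from the statistic
#'
#' Computes the exact null distribution of the Mann-Whitney U statistic by
#' the partition-count recurrence (integer-exact until the final division),
#' assuming no ties. The one-sided p is the cumulative arrangement count of
#' the smaller tail, `min(U, n1*n2 - U)`, divided by `choose(n1 + n2, n1)`;
#' the two-sided p is twice that, clamped at 1 (no mid-p correction).
#' `method = "normal_approx"` uses the large-sample normal approximation
#' with continuity correction instead.
#'
#' @param U the observed statistic, in `[0, n1 * n2]`.
#' @param n1,n2 group sizes.
#' @param method `"exact"` or `"normal_approx"`.
#' @param medians optional group medians to carry along.
#' @return an [ExactTestResult-class].
#' @examples
#' pValue(mannWhitneyExact(0, 26, 11))  # 2.339e-9
#' @export
mannWhitneyExact <- function(U, n1, n2, method = c("exact", "normal_approx"),
                             medians = c(NA_real_, NA_real_)) {
  method <- match.arg(method)
  n1 <- as.integer(n1); n2 <- as.integer(n2)
  stopifnot(n1 >= 1L, n2 >= 1L)
  if (U < 0 || U > n1 * n2) stop("U must lie in [0, n1 * n2]")
  if (U != round(U)) stop("U must be an integer")
  u <- min(U, n1 * n2 - U)
  if (method == "exact") {
    counts <- .mwCounts(n1, n2)
    total <- choose(n1 + n2, n1)
    stopifnot(sum(counts) == total)
    p1 <- sum(counts[seq_len(u + 1L)]) / total
  } else {
    mu <- n1 * n2 / 2
    sigma <- sqrt(n1 * n2 * (n1 + n2 + 1) / 12)
    p1 <- stats::pnorm((u + 0.5 - mu) / sigma)
  }
  new("ExactTestResult",
      U = as.numeric(U), n1 = n1, n2 = n2,
      pOneSided = p1, pTwoSided = min(1, 2 * p1),
      method = method, medians = as.numeric(medians))
}

#' Mann-Whitney test from raw samples
#'
#' Computes U as the number of (x, y) pairs with x below y (rank-based; so
#' U = 0 when every value of `x` exceeds every value of `y`) and delegates
#' to [mannWhitneyExact()]. Ties are not supported by the exact
#' distribution and raise an error.
#'
#' @param x,y numeric samples (group 1 and group 2).
#' @param method passed to [mannWhitneyExact()].
#' @return an [ExactTestResult-class] with group medians filled in.
#' @export
mannWhitneyU <- function(x, y, method = c("exact", "normal_approx")) {
  stopifnot(length(x) >= 1L, length(y) >= 1L)
  z <- c(x, y)
  if (anyDuplicated(z)) {
    stop("ties between or within samples are not supported by the exact test")
  }
  n1 <- length(x); n2 <- length(y)
  r <- rank(z)
  U1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2  # pairs with x > y
  U <- n1 * n2 - U1                              # pairs with x < y
  mannWhitneyExact(U, n1, n2, method = match.arg(method),
                   medians = c(stats::median(x), stats::median(y)))
}

# round half up, the convention used for printed percentages
.roundHalfUp <- function(x, digits = 1L) {
  floor(x * 10^digits + 0.5) / 10^digits
}

#' Percent of targeted sequencing depth
#'
#' @param observedReads observed read count.
#' @param targetReads targeted read count (> 0).
#' @return observed / target x 100, rounded half-up to one decimal.
#' @examples
#' percentOfTarget(44554464, 50e6)  # 89.1
#' @export
percentOfTarget <- function(observedReads, targetReads) {
  if (any(targetReads <= 0)) stop("targetReads must be > 0")
  .roundHalfUp(observedReads / targetReads * 100, 1L)
}
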