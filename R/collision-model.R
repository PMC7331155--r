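# Cross-sample barcode collision under index hopping.
#
# In a single-indexed pool, a hopped read cannot be told apart from a
# legitimate one, so any cell barcode that is either (i) shared with another
# cell anywhere in the pool or (ii) hit by an index hop must be discarded.
# Because hopping makes every read equally likely to claim any sample, all
# pooled cells are treated as one sample when computing collisions.

#' @rdname PoolConfig-class
#' @param nSamples number of pooled samples.
#' @param cellsPerSample cells per sample (default 3000).
#' @param barcodeSpace number of distinct cell barcodes available
#'   (default 147456 = 384 x 384).
#' @param hopRate per-cell index hopping probability (default 0.0485).
#' @export
PoolConfig <- function(nSamples, cellsPerSample = 3000L,
                       barcodeSpace = 147456L, hopRate = 0.0485) {
  new("PoolConfig",
      nSamples = as.integer(nSamples),
      cellsPerSample = as.integer(cellsPerSample),
      barcodeSpace = as.integer(barcodeSpace),
      hopRate = as.numeric(hopRate))
}

#' Probability of a cross-pool barcode collision
#'
#' Probability that a given cell shares its barcode with at least one other
#' of the `totalCells` cells in the pool, under uniform independent barcode
#' draws from a space of `barcodeSpace` barcodes:
#' `1 - (1 - 1/N)^(k - 1)`.
#'
#' @param totalCells pooled cell count k (>= 1).
#' @param barcodeSpace barcode space size N (>= 1).
#' @return collision probability.
#' @examples
#' pBarcodeCollision(3, 4)                 # 0.4375
#' pBarcodeCollision(6000, 147456)         # ~0.0399
#' @export
pBarcodeCollision <- function(totalCells, barcodeSpace) {
  if (totalCells < 1L || barcodeSpace < 1L) {
    stop("totalCells and barcodeSpace must be >= 1")
  }
  1 - (1 - 1 / barcodeSpace)^(totalCells - 1)
}

#' Fraction of cell barcodes discarded in a single-indexed pool
#'
#' Barcode collision and index hopping are modeled as independent events;
#' the probability that either strikes a cell is combined by
#' inclusion-exclusion: `P(collision) + h - P(collision) * h`. This is the
#' fraction of cell barcodes (hence cells) that must be discarded from a
#' single-indexed pool.
#'
#' @param config a [PoolConfig-class], or the number of samples (then the
#'   remaining parameters are taken from the defaults of [PoolConfig()]).
#' @param ... passed to [PoolConfig()] when `config` is a sample count.
#' @return discard probability.
#' @examples
#' pDiscard(PoolConfig(nSamples = 2))  # ~0.0864 (printed as 8.67%)
#' @export
pDiscard <- function(config, ...) {
  if (!is(config, "PoolConfig")) config <- PoolConfig(config, ...)
  k <- config@nSamples * config@cellsPerSample
  pc <- pBarcodeCollision(k, config@barcodeSpace)
  h <- config@hopRate
  pc + h - pc * h
}

#' Discard fractions across pool sizes
#'
#' @param poolSizes integer vector of sample counts per pool.
#' @param cellsPerSample,barcodeSpace,hopRate model parameters, see
#'   [PoolConfig()].
#' @return data frame with one row per pool size: `nSamples`, `totalCells`,
#'   `pCollision`, `pDiscard`; `pDiscard` is nondecreasing in pool size.
#' @examples
#' discardCurve(c(2, 4, 12, 24, 48))
#' @export
discardCurve <- function(poolSizes, cellsPerSample = 3000L,
                         barcodeSpace = 147456L, hopRate = 0.0485) {
  if (length(poolSizes) == 0L) {
    return(data.frame(nSamples = integer(0), totalCells = integer(0),
                      pCollision = numeric(0), pDiscard = numeric(0)))
  }
  stopifnot(all(poolSizes >= 1L))
  rows <- lapply(poolSizes, function(s) {
    cfg <- PoolConfig(s, cellsPerSample, barcodeSpace, hopRate)
    k <- cfg@nSamples * cfg@cellsPerSample
    data.frame(nSamples = s, totalCells = k,
               pCollision = pBarcodeCollision(k, barcodeSpace),
               pDiscard = pDiscard(cfg))
  })
  do.call(rbind, rows)
}

#' Monte-Carlo estimate of the discarded barcode fraction
#'
#' Simulates `nPools` independent pools. Each cell draws a barcode uniformly
#' from the barcode space; a cell is discarded when its barcode is
#' duplicated within the pool or an independent Bernoulli(hop rate) hop
#' event fires. Serves as the stochastic check of the analytic
#' [pDiscard()] model.
#'
#' @param config a [PoolConfig-class].
#' @param nPools number of replicate pools (>= 1).
#' @param seed RNG seed; identical seeds reproduce the estimate exactly.
#' @return a [CollisionEstimate-class] carrying both the analytic values and
#'   the Monte-Carlo mean and standard error.
#' @examples
#' mcDiscard(PoolConfig(2), nPools = 50, seed = 1)
#' @export
mcDiscard <- function(config, nPools, seed) {
  stopifnot(is(config, "PoolConfig"), nPools >= 1L)
  set.seed(seed)
  k <- config@nSamples * config@cellsPerSample
  N <- config@barcodeSpace
  h <- config@hopRate
  frac <- vapply(seq_len(nPools), function(i) {
    bc <- sample.int(N, k, replace = TRUE)
    dup <- tabulate(bc, nbins = N)[bc] > 1L
    hop <- stats::runif(k) < h
    mean(dup | hop)
  }, numeric(1))
  new("CollisionEstimate",
      pCollision = pBarcodeCollision(k, N),
      pDiscard = pDiscard(config),
      mcMean = mean(frac),
      mcStderr = if (nPools > 1L) stats::sd(frac) / sqrt(nPools) else NA_real_,
      nReplicateCells = as.numeric(k) * nPools,
      seed = as.numeric(seed))
}
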