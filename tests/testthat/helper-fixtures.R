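# Fixtures shared across test files, built in code.

# The two dual-indexed samples of the published NovaSeq run.
truDropSheet <- function() {
  SampleSheet(c("Mouse4", "Mouse5"),
              i7 = c("CCGCGGTT", "TTATAACC"),
              i5 = c("AGCGCTAG", "GATATCGA"))
}

# Single-indexed V2 samples (note: the published sheet mixes 8- and 6-base
# i7 indexes).
v2SingleSheet <- function() {
  SampleSheet(c("Mouse2", "Mouse3"),
              i7 = c("GATATCGA", "GCCAAT"),
              i5 = NULL)
}

v2SingleSheetUniform <- function() {
  SampleSheet(c("Mouse2", "Mouse3"), i7 = c("GATATC", "GCCAAT"), i5 = NULL)
}

# A unique-dual sheet of n samples whose indexes keep pairwise edit
# distance >= 2 on each side; deterministic under the seed.
syntheticUniqueDualSheet <- function(n, width = 8L, seed = 97L) {
  set.seed(seed)
  pickSet <- function() {
    chosen <- character(0)
    while (length(chosen) < n) {
      cand <- paste(sample(c("A", "C", "G", "T"), width, replace = TRUE),
                    collapse = "")
      if (all(nchar(chosen) == 0L) ||
          all(utils::adist(cand, chosen) >= 2L)) {
        chosen <- c(chosen, cand)
      }
    }
    chosen
  }
  SampleSheet(sprintf("S%02d", seq_len(n)), i7 = pickSet(), i5 = pickSet())
}

randomDNAString <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
}

# Normalization used when comparing rendered templates against printed
# template strings: drop whitespace, lower-case the bracketed tokens (the
# printed templates mix token capitalization).
normalizeTemplate <- function(x) {
  x <- gsub("\\s+", "", x)
  m <- gregexpr("\\[[^]]*\\]", x)
  regmatches(x, m) <- lapply(regmatches(x, m), tolower)
  x
}

# Brute-force exact Mann-Whitney null distribution by enumerating all
# arrangements of group labels; counts indexed by U = 0..n1*n2.
bruteForceMWCounts <- function(n1, n2) {
  n <- n1 + n2
  counts <- numeric(n1 * n2 + 1L)
  combos <- utils::combn(n, n1)
  for (j in seq_len(ncol(combos))) {
    u <- sum(combos[, j]) - n1 * (n1 + 1) / 2
    counts[u + 1L] <- counts[u + 1L] + 1
  }
  counts
}
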