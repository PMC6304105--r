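## Independent per-base / enumeration oracles used by the property tests.
## These deliberately use naive representations (logical bitmaps, double
## loops) so they share no code path with the implementation they check.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(Biostrings)
})

# occupancy bitmap of a GRanges on one chromosome of length L
bitmapOf <- function(gr, L) {
  bm <- logical(L)
  for (i in seq_along(gr)) bm[start(gr)[i]:end(gr)[i]] <- TRUE
  bm
}

# union with gap closing: any run of FALSE of length <= joinGap flanked by
# TRUE becomes TRUE; then extract maximal TRUE runs
bitmapMerge <- function(gr, L, joinGap) {
  bm <- bitmapOf(gr, L)
  r <- rle(bm)
  ends <- cumsum(r$lengths)
  for (k in seq_along(r$lengths)) {
    if (!r$values[k] && r$lengths[k] <= joinGap &&
        k > 1 && k < length(r$lengths))
      bm[(ends[k] - r$lengths[k] + 1):ends[k]] <- TRUE
  }
  bitmapToRanges(bm)
}

bitmapToRanges <- function(bm) {
  r <- rle(bm)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  cbind(start = starts[r$values], end = ends[r$values])
}

# random interval set on a single chromosome
randomIntervals <- function(n, L, maxLen = 200) {
  s <- sample.int(L - maxLen, n, replace = TRUE)
  w <- sample.int(maxLen, n, replace = TRUE)
  GRanges("chr1", IRanges(s, s + w - 1))
}

rangesMatrix <- function(gr) {
  if (length(gr) == 0L) return(cbind(start = integer(), end = integer()))
  m <- cbind(start = start(gr), end = end(gr))
  m[order(m[, 1]), , drop = FALSE]
}

# brute-force N(x): the largest L such that sum(lengths >= L) >= x% of total
nxBrute <- function(lengths, x) {
  total <- sum(lengths)
  cand <- sort(unique(lengths), decreasing = TRUE)
  for (L in cand) if (sum(lengths[lengths >= L]) * 100 >= x * total) return(L)
  min(lengths)
}

# brute-force support-window marking: every run of exactly `win` columns
# with >= minId matches marks its columns (double loop, no cumsums)
markWindowsBrute <- function(isMatch, win, minId) {
  n <- length(isMatch)
  marked <- logical(n)
  if (n >= win) for (i in 1:(n - win + 1)) {
    if (sum(isMatch[i:(i + win - 1)]) / win >= minId)
      marked[i:(i + win - 1)] <- TRUE
  }
  marked
}

# brute-force entropy-quality check over all windows of length >= minLen
entropyQualityBrute <- function(ref, qry, minLen = 30, minId = 0.6,
                                minEnt = 1.8) {
  r <- strsplit(toupper(ref), "")[[1]]
  q <- strsplit(toupper(qry), "")[[1]]
  n <- length(r)
  if (n < minLen) return(FALSE)
  for (i in 1:(n - minLen + 1)) for (j in (i + minLen - 1):n) {
    rr <- r[i:j]; qq <- q[i:j]
    id <- sum(rr == qq & rr != "-") / (j - i + 1)
    if (id < minId) next
    bases <- qq[qq != "-"]
    if (length(bases) == 0) next
    p <- table(bases) / length(bases)
    H <- -sum(p * log2(p))
    if (H >= minEnt) return(TRUE)
  }
  FALSE
}

randomSeqChars <- function(n) sample(c("A", "C", "G", "T"), n, replace = TRUE)

randomSeqStr <- function(n) paste(randomSeqChars(n), collapse = "")

# small simulated clade shared by several test files (cheap config)
smallCladeConfig <- function(seed = 11, ...) {
  simulationConfig(seed = seed, genomeLen = 40000L, nElements = 12L,
                   elementLenRange = c(120L, 250L), nExons = 6L,
                   exonOverlapCount = 1L, nTransposons = 6L,
                   transposonOverlapCount = 2L, ...)
}
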