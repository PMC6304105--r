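#' Locate assembly gaps
#'
#' Finds maximal runs of `N`/`n` of length at least `minRun` in every
#' scaffold. Runs shorter than `minRun` are not reported; they are treated
#' as ordinary ambiguous bases, not assembly gaps.
#'
#' @param assembly a named `BStringSet` (see [readGenome()]).
#' @param minRun minimum N-run length that counts as a gap (default 25).
#' @return a `GRanges` of gap intervals with seqlengths set.
#' @export
findGaps <- function(assembly, minRun = 25L) {
  minRun <- .assertCount(minRun, "minRun", min = 1)
  pat <- sprintf("[Nn]{%d,}", minRun)
  seqs <- as.character(assembly)
  hits <- gregexpr(pat, seqs)
  res <- lapply(seq_along(seqs), function(i) {
    m <- hits[[i]]
    if (m[1L] == -1L) return(NULL)
    GenomicRanges::GRanges(names(seqs)[i],
      IRanges::IRanges(as.integer(m), width = attr(m, "match.length")))
  })
  res <- res[!vapply(res, is.null, TRUE)]
  gr <- if (length(res)) do.call(c, res) else GenomicRanges::GRanges()
  GenomeInfoDb::seqlevels(gr) <- names(assembly)
  GenomeInfoDb::seqlengths(gr) <- Biostrings::width(assembly)
  gr
}

#' Split scaffolds into contigs at assembly gaps
#'
#' Each scaffold is split at its [findGaps()] intervals; the resulting
#' gap-free pieces are the contigs. Zero-length pieces (e.g. a scaffold
#' starting with a gap) are discarded, so
#' `sum(contig lengths) == total bases - gap bases` always holds.
#'
#' @inheritParams findGaps
#' @return integer vector of contig lengths.
#' @export
splitIntoContigs <- function(assembly, minRun = 25L) {
  gaps <- findGaps(assembly, minRun)
  pieces <- GenomicRanges::gaps(gaps)  # complement within seqlengths
  pieces <- pieces[GenomicRanges::strand(pieces) == "*"]
  as.integer(GenomicRanges::width(pieces))
}

#' N(x) assembly statistics
#'
#' `nxValue(lengths, x)` is the largest length L such that the sequences of
#' length >= L together cover at least x% of the total assembly: sort the
#' lengths in descending order, take the cumulative sum, and return the
#' length at which the cumulative sum first reaches x% of the total. N50 and
#' N90 are `x = 50` and `x = 90`. The percentage threshold is compared as
#' `100 * cumsum >= x * total` in exact integer arithmetic so ties at the
#' boundary are reproducible.
#'
#' @param lengths positive sequence lengths (non-empty).
#' @param x integer percentage in 1..99.
#' @return `nxValue`: a single length; `nxCurve`: a data.frame with columns
#'   `x` (1..99) and `value`, non-increasing in `x`.
#' @examples
#' nxValue(c(8, 5, 3, 2), 50)  # 5
#' nxValue(c(8, 5, 3, 2), 90)  # 2
#' @export
nxValue <- function(lengths, x) {
  x <- .assertCount(x, "x", min = 1)
  if (x > 99) stop("'x' must be in 1..99", call. = FALSE)
  .nxSeries(lengths, x)[[1L]]
}

#' @rdname nxValue
#' @export
nxCurve <- function(lengths) {
  data.frame(x = 1:99, value = .nxSeries(lengths, 1:99))
}

.nxSeries <- function(lengths, xs) {
  if (length(lengths) == 0L) stop("'lengths' must be non-empty", call. = FALSE)
  if (any(lengths <= 0)) stop("'lengths' must be positive", call. = FALSE)
  srt <- sort(as.numeric(lengths), decreasing = TRUE)
  cs <- cumsum(srt)
  total <- cs[length(cs)]
  # first index where 100*cumsum >= x*total; integer-valued doubles are exact
  vapply(xs, function(x) srt[which(100 * cs >= x * total)[1L]], 0)
}

#' Soft-masked fraction of an assembly
#'
#' Fraction of lowercase (soft-masked) bases over all bases. `N` bases count
#' in the denominator only (lowercase `n` counts as masked), matching the
#' convention of reporting repeat content as a proportion of the genome.
#'
#' @param assembly a `BStringSet`.
#' @return a fraction in \[0, 1\].
#' @export
maskedFraction <- function(assembly) {
  total <- sum(as.numeric(Biostrings::width(assembly)))
  if (total == 0) return(0)
  lower <- sum(as.numeric(Biostrings::letterFrequency(assembly, "acgtn")))
  lower / total
}

#' Full assembly summary report
#'
#' Computes total and gap bases, scaffold/contig counts, the complete N(x)
#' series at scaffold and contig level, and the soft-masked fraction.
#'
#' @inheritParams findGaps
#' @return an [AssemblyReport-class] object.
#' @export
assemblyReport <- function(assembly, minRun = 25L) {
  minRun <- .assertCount(minRun, "minRun", min = 1)
  scafLens <- as.numeric(Biostrings::width(assembly))
  gaps <- findGaps(assembly, minRun)
  contigLens <- splitIntoContigs(assembly, minRun)
  nx <- function(l) setNames(.nxSeries(l, 1:99), 1:99)
  new("AssemblyReport",
      totalBases = sum(scafLens),
      gapBases = sum(as.numeric(GenomicRanges::width(gaps))),
      nScaffolds = length(assembly),
      nContigs = length(contigLens),
      scaffoldNx = nx(scafLens),
      contigNx = if (length(contigLens)) nx(contigLens) else setNames(rep(0, 99), 1:99),
      maskedFraction = maskedFraction(assembly),
      minGapRun = minRun)
}
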