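#' Interval arithmetic on genomic ranges
#'
#' Thin, strand-agnostic wrappers around the `GenomicRanges` interval
#' algebra, with the gap-joining convention used throughout the CNE
#' pipeline: the gap between two intervals is the number of bases strictly
#' between them, so abutting intervals have gap 0 and are always joined.
#'
#' @param gr,a,b `GRanges` inputs. Strand is carried along where possible
#'   but never used for arithmetic.
#' @param joinGap integer >= 0; intervals on the same sequence separated by
#'   at most this many bases are unioned (default 0: only overlapping or
#'   abutting intervals merge).
#' @return `mergeIntervals` and `subtractIntervals` return a sorted,
#'   per-sequence non-overlapping `GRanges`; `overlapLength` an integer
#'   vector; `coveredBases` a single number.
#' @examples
#' library(GenomicRanges)
#' gr <- GRanges("chr1", IRanges(c(1, 46), c(40, 60)))
#' width(mergeIntervals(gr, joinGap = 10))  # 60: gap of 5 <= 10
#' @name interval-ops
NULL

#' @rdname interval-ops
#' @export
mergeIntervals <- function(gr, joinGap = 0L) {
  joinGap <- .assertCount(joinGap, "joinGap")
  GenomicRanges::reduce(gr, min.gapwidth = joinGap + 1L, ignore.strand = TRUE)
}

#' @rdname interval-ops
#' @export
subtractIntervals <- function(a, b) {
  lv <- union(GenomeInfoDb::seqlevels(a), GenomeInfoDb::seqlevels(b))
  GenomeInfoDb::seqlevels(a) <- lv
  GenomeInfoDb::seqlevels(b) <- lv
  GenomicRanges::setdiff(a, b, ignore.strand = TRUE)
}

#' @rdname interval-ops
#' @export
overlapLength <- function(a, b) {
  stopifnot(length(a) == length(b))
  if (length(a) == 0L) return(integer())
  same <- as.character(GenomicRanges::seqnames(a)) ==
    as.character(GenomicRanges::seqnames(b))
  ol <- pmin(GenomicRanges::end(a), GenomicRanges::end(b)) -
    pmax(GenomicRanges::start(a), GenomicRanges::start(b)) + 1L
  as.integer(ifelse(same, pmax(0L, ol), 0L))
}

#' @rdname interval-ops
#' @export
coveredBases <- function(gr) {
  sum(as.numeric(GenomicRanges::width(GenomicRanges::reduce(gr, ignore.strand = TRUE))))
}
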