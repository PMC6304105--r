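#' Prepare a CNE reference set
#'
#' Conserved non-exonic elements are prepared for completeness scoring by
#' keeping only elements longer than `minLen - 1` bases (the default keeps
#' elements longer than 300 bp, strictly) and trimming `trim` bases from
#' both ends, because the element core is what stays conserved over large
#' evolutionary distances. With the defaults every prepared element is at
#' least 241 bp.
#'
#' @param elements named `BStringSet` of raw element sequences.
#' @param minLen minimum retained input length (default 301, i.e. "> 300 bp").
#' @param trim bases removed from each end (default 30).
#' @return trimmed `BStringSet`, ids preserved, input order preserved.
#' @export
prepareCneReference <- function(elements, minLen = 301L, trim = 30L) {
  minLen <- .assertCount(minLen, "minLen", min = 1)
  trim <- .assertCount(trim, "trim")
  if (minLen <= 2L * trim)
    stop("'minLen' must exceed 2 * trim", call. = FALSE)
  keep <- Biostrings::width(elements) >= minLen
  out <- elements[keep]
  if (length(out) && trim > 0L)
    out <- Biostrings::subseq(out, start = trim + 1L,
                              end = Biostrings::width(out) - trim)
  out
}

#' Filter hits and keep the best one per element
#'
#' Removes hits failing the identity or coverage thresholds (both
#' inclusive: a hit at exactly 60% identity and 80% coverage passes), then
#' retains a single best hit per element. Ranking is deterministic and
#' input-order independent: by identity x coverage, ties broken by more
#' matches, remaining ties by lexicographically smallest (target sequence,
#' start).
#'
#' @param hits a hit `GRanges` (from [mapElements()] or [readPaf()]).
#' @param minIdentity,minCoverage inclusive thresholds (defaults 0.60, 0.80).
#' @param identityMode identity denominator convention, see [hitIdentity()].
#' @return hit `GRanges` with one row per surviving element, plus
#'   `identity` and `coverage` metadata columns.
#' @export
filterHits <- function(hits, minIdentity = 0.60, minCoverage = 0.80,
                       identityMode = c("gap-inclusive", "gap-exclusive")) {
  identityMode <- match.arg(identityMode)
  minIdentity <- .assertFraction(minIdentity, "minIdentity")
  minCoverage <- .assertFraction(minCoverage, "minCoverage")
  if (length(hits) == 0L) {
    hits$identity <- numeric(); hits$coverage <- numeric()
    return(hits)
  }
  id <- hitIdentity(hits, identityMode)
  cov <- hitCoverage(hits)
  keep <- id >= minIdentity & cov >= minCoverage
  hits <- hits[keep]; id <- id[keep]; cov <- cov[keep]
  hits$identity <- id; hits$coverage <- cov
  if (length(hits) == 0L) return(hits)
  ord <- order(hits$query_id,
               -id * cov, -hits$matches,
               as.character(GenomicRanges::seqnames(hits)),
               GenomicRanges::start(hits))
  hits <- hits[ord]
  hits[!duplicated(hits$query_id)]
}

#' Score assembly completeness over a reference element set
#'
#' Counts how many reference elements were recovered by a hit surviving
#' [filterHits()] and reports both partitions (found / missing) with the
#' best hit per found element.
#'
#' @param elements a named `BStringSet` or character vector of element ids.
#' @param filteredHits output of [filterHits()] (one best hit per element).
#' @return a [CompletenessReport-class].
#' @export
scoreCompleteness <- function(elements, filteredHits) {
  ids <- if (is.character(elements)) elements else names(elements)
  if (is.null(ids) || any(!nzchar(ids)))
    stop("elements must be named or a character vector of ids", call. = FALSE)
  unknown <- setdiff(filteredHits$query_id, ids)
  if (length(unknown))
    stop("hit(s) for unknown element id(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  found <- ids[ids %in% filteredHits$query_id]
  missing <- setdiff(ids, found)
  m <- match(found, filteredHits$query_id)
  hits <- S4Vectors::DataFrame(
    element = found,
    identity = filteredHits$identity[m],
    coverage = filteredHits$coverage[m],
    seqnames = as.character(GenomicRanges::seqnames(filteredHits))[m],
    start = GenomicRanges::start(filteredHits)[m],
    end = GenomicRanges::end(filteredHits)[m],
    strand = as.character(GenomicRanges::strand(filteredHits))[m])
  new("CompletenessReport", nTotal = length(ids), nFound = length(found),
      foundIds = found, missingIds = missing, hits = hits)
}
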