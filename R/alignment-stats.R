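.checkAlignedPair <- function(ref, qry) {
  stopifnot(is.character(ref), is.character(qry),
            length(ref) == 1L, length(qry) == 1L)
  if (nchar(ref) != nchar(qry))
    stop("aligned rows have unequal length", call. = FALSE)
  if (nchar(ref) == 0L) stop("empty alignment", call. = FALSE)
  list(r = strsplit(toupper(ref), "")[[1L]], q = strsplit(toupper(qry), "")[[1L]])
}

#' Alignment quality filter: identity and entropy over a window
#'
#' Tests whether a pairwise aligned region contains at least one contiguous
#' run of `minLen` or more columns with (a) sequence identity at least
#' `minId` and (b) Shannon entropy of the base composition of at least
#' `minEntropyBits`. The entropy H = -sum(p_b log2 p_b) is computed over
#' the composition of the *query* bases of the run, gap columns excluded,
#' so runs of near-homopolymer sequence cannot pass on identity alone.
#' This is the standard filter used to discard spurious local alignments.
#'
#' @param ref,qry equal-length aligned strings ("-" for gaps); `ref` is the
#'   reference row, `qry` the query row whose composition is scored.
#' @param minLen minimum run length in columns (default 30).
#' @param minId minimum identity, matches / run columns (default 0.60).
#' @param minEntropyBits minimum composition entropy in bits (default 1.8).
#' @return `TRUE` if any qualifying run exists.
#' @examples
#' passesEntropyQuality(strrep("A", 30), strrep("A", 30))  # FALSE: H = 0
#' s <- strrep("ACGT", 8)
#' passesEntropyQuality(s, s)                              # TRUE: H = 2 bits
#' @export
passesEntropyQuality <- function(ref, qry, minLen = 30L, minId = 0.60,
                                 minEntropyBits = 1.8) {
  minLen <- .assertCount(minLen, "minLen", min = 1)
  p <- .checkAlignedPair(ref, qry)
  n <- length(p$r)
  if (n < minLen) return(FALSE)
  isMatch <- p$r == p$q & p$r != "-"
  csM <- c(0, cumsum(isMatch))
  bases <- c("A", "C", "G", "T")
  csB <- sapply(bases, function(b) c(0, cumsum(p$q == b)))
  csO <- c(0, cumsum(p$q != "-" & !(p$q %in% bases)))  # N etc.: own category
  for (i in seq_len(n - minLen + 1L)) {
    ends <- (i + minLen - 1L):n
    len <- ends - i + 1L
    idOK <- (csM[ends + 1L] - csM[i]) / len >= minId
    if (!any(idOK)) next
    ends <- ends[idOK]
    cnt <- cbind(csB[ends + 1L, , drop = FALSE] -
                   rep(csB[i, ], each = length(ends)),
                 csO[ends + 1L] - csO[i])
    tot <- rowSums(cnt)
    ok <- tot > 0
    if (!any(ok)) next
    pfrac <- cnt[ok, , drop = FALSE] / tot[ok]
    H <- -rowSums(ifelse(pfrac > 0, pfrac * log2(pfrac), 0))
    if (any(H >= minEntropyBits)) return(TRUE)
  }
  FALSE
}

#' Column-wise difference summary of a pairwise alignment
#'
#' Classifies every alignment column exactly once: both bases present and
#' equal (match) or unequal (substitution); base only in the query
#' (insertion relative to the reference); base only in the reference
#' (deletion). The percentage breakdown is reported over reference
#' (first-genome) bases, the convention used when summarizing how much of
#' one assembly version changed in the next.
#'
#' @param ref,qry equal-length aligned strings; `ref` is the reference.
#' @return a [ColumnPairStats-class] object.
#' @details A column with gaps on both rows is malformed and rejected.
#'   Matching is case-insensitive (soft-masking does not create
#'   differences).
#' @export
summarizeDifferences <- function(ref, qry) {
  p <- .checkAlignedPair(ref, qry)
  rGap <- p$r == "-"; qGap <- p$q == "-"
  if (any(rGap & qGap))
    stop("malformed alignment: column with gaps on both rows", call. = FALSE)
  match <- sum(!rGap & !qGap & p$r == p$q)
  mism <- sum(!rGap & !qGap & p$r != p$q)
  ins <- sum(rGap & !qGap)
  del <- sum(!rGap & qGap)
  refBases <- match + mism + del
  pct <- c(match = 100 * match / refBases,
           substitution = 100 * mism / refBases,
           insertion = 100 * ins / refBases,
           deletion = 100 * del / refBases)
  new("ColumnPairStats", columns = length(p$r), match = match,
      mismatch = mism, ins = as.integer(ins), del = as.integer(del),
      refBases = as.integer(refBases), percentages = pct)
}
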