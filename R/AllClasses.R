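#' @import methods
#' @importFrom S4Vectors DataFrame
NULL

#' AssemblyReport: summary statistics of one genome assembly
#'
#' Holds the standard contiguity and composition summaries of an assembly:
#' total and gap bases, scaffold and contig counts, the full N(x) series for
#' x = 1..99 at both scaffold and contig level, and the soft-masked
#' (lowercase) fraction. Created by [assemblyReport()].
#'
#' @slot totalBases total assembly length in bases.
#' @slot gapBases bases inside assembly gaps (runs of >= minGapRun Ns).
#' @slot nScaffolds,nContigs sequence counts before/after splitting at gaps.
#' @slot scaffoldNx,contigNx named numeric vectors, N(x) for x = 1..99.
#' @slot maskedFraction fraction of lowercase (soft-masked) bases.
#' @slot minGapRun the N-run length threshold used to define gaps.
#' @name AssemblyReport-class
#' @aliases AssemblyReport
#' @exportClass AssemblyReport
setClass("AssemblyReport", representation(
  totalBases = "numeric", gapBases = "numeric",
  nScaffolds = "integer", nContigs = "integer",
  scaffoldNx = "numeric", contigNx = "numeric",
  maskedFraction = "numeric", minGapRun = "integer"
))

setValidity("AssemblyReport", function(object) {
  msg <- character()
  if (object@gapBases > object@totalBases)
    msg <- c(msg, "gapBases exceeds totalBases")
  if (object@maskedFraction < 0 || object@maskedFraction > 1)
    msg <- c(msg, "maskedFraction outside [0, 1]")
  for (nm in c("scaffoldNx", "contigNx")) {
    nx <- slot(object, nm)
    if (length(nx) && is.unsorted(rev(nx)))
      msg <- c(msg, sprintf("%s must be non-increasing in x", nm))
  }
  if (length(msg)) msg else TRUE
})

#' MafBlock: one block of a reference-anchored multiple alignment
#'
#' A single MAF alignment block: per-species rows of equal aligned width with
#' their source coordinates (MAF semantics: `start` is 0-based on the source
#' strand, `srcSize` is the full source sequence length). The first row is
#' the reference row.
#'
#' @slot src character, per-row source names ("species.chrom").
#' @slot start integer, 0-based start on the source strand.
#' @slot size integer, ungapped row length.
#' @slot strand character, "+" or "-" per row.
#' @slot srcSize integer, full length of each row's source sequence.
#' @slot text character, aligned row text with "-" gaps.
#' @name MafBlock-class
#' @aliases MafBlock
#' @exportClass MafBlock
setClass("MafBlock", representation(
  src = "character", start = "integer", size = "integer",
  strand = "character", srcSize = "integer", text = "character"
))

setValidity("MafBlock", function(object) {
  n <- length(object@src)
  msg <- character()
  if (n < 1L) msg <- c(msg, "block must contain at least one row")
  if (any(lengths(list(object@start, object@size, object@strand,
                       object@srcSize, object@text)) != n))
    msg <- c(msg, "all row slots must have equal length")
  w <- nchar(object@text)
  if (length(unique(w)) > 1L)
    msg <- c(msg, "rows of unequal aligned length within a block")
  ungapped <- nchar(gsub("-", "", object@text, fixed = TRUE))
  if (!all(ungapped == object@size))
    msg <- c(msg, "row size inconsistent with ungapped text length")
  if (!all(object@strand %in% c("+", "-")))
    msg <- c(msg, "strand must be '+' or '-'")
  if (length(msg)) msg else TRUE
})

#' ColumnPairStats: classified columns of one pairwise alignment
#'
#' Column-wise classification of a pairwise alignment into matches,
#' mismatches (substitutions), insertions (base only in the second genome)
#' and deletions (base only in the first, reference genome), with the
#' percentage breakdown over reference bases. Created by
#' [summarizeDifferences()].
#'
#' @slot columns,match,mismatch,ins,del integer column counts.
#' @slot refBases number of reference (first-genome) bases, the
#'   denominator of the percentage breakdown.
#' @slot percentages named numeric: match, substitution, insertion,
#'   deletion percentages over reference bases.
#' @name ColumnPairStats-class
#' @aliases ColumnPairStats
#' @exportClass ColumnPairStats
setClass("ColumnPairStats", representation(
  columns = "integer", match = "integer", mismatch = "integer",
  ins = "integer", del = "integer", refBases = "integer",
  percentages = "numeric"
))

setValidity("ColumnPairStats", function(object) {
  if (object@match + object@mismatch + object@ins + object@del != object@columns)
    return("match + mismatch + ins + del must equal columns")
  TRUE
})

#' CompletenessReport: element recovery under identity/coverage filters
#'
#' Result of scoring assembly completeness against a reference set of
#' conserved elements: how many elements were recovered by an alignment
#' passing the identity and coverage thresholds, which ones were missed, and
#' the best hit per recovered element. Created by [scoreCompleteness()].
#'
#' @slot nTotal,nFound element counts.
#' @slot foundIds,missingIds the two id partitions.
#' @slot hits DataFrame, one row per found element: element, identity,
#'   coverage, target seqname/start/end/strand.
#' @name CompletenessReport-class
#' @aliases CompletenessReport
#' @exportClass CompletenessReport
setClass("CompletenessReport", representation(
  nTotal = "integer", nFound = "integer",
  foundIds = "character", missingIds = "character", hits = "DataFrame"
))

setValidity("CompletenessReport", function(object) {
  msg <- character()
  if (object@nFound + length(object@missingIds) != object@nTotal)
    msg <- c(msg, "nFound + |missingIds| must equal nTotal")
  if (length(object@foundIds) != object@nFound)
    msg <- c(msg, "|foundIds| must equal nFound")
  if (length(msg)) msg else TRUE
})

#' ContiguityReport: recovery of conserved neighboring element pairs
#'
#' Result of the synteny-based contiguity statistic: for each evolutionarily
#' conserved pair of neighboring elements, whether both members were found
#' on one scaffold within the distance bound (`recovered`), on different
#' scaffolds or too far apart (`split`), or not both mapped (`unmapped`).
#' Created by [evaluatePairs()].
#'
#' @slot nPairs,nRecovered pair counts.
#' @slot fraction nRecovered / nPairs (raw, unrounded).
#' @slot detail DataFrame, one row per pair: elementA, elementB, status,
#'   targetA, targetB, distance.
#' @name ContiguityReport-class
#' @aliases ContiguityReport
#' @exportClass ContiguityReport
setClass("ContiguityReport", representation(
  nPairs = "integer", nRecovered = "integer",
  fraction = "numeric", detail = "DataFrame"
))

setValidity("ContiguityReport", function(object) {
  if (object@nRecovered < 0L || object@nRecovered > object@nPairs)
    return("nRecovered must lie in [0, nPairs]")
  TRUE
})

#' TransposonOverlapReport: transposon-derived fraction of a CNE set
#'
#' Accounting of overlap between conserved non-exonic elements and
#' transposon annotations (SINE, LINE, LTR, DNA classes): how many CNEs
#' overlap a single transposon feature by at least the threshold, the summed
#' overlapped bases, the per-class base share, and the fraction of all CNE
#' bases explained by transposons. Created by [transposonOverlap()].
#'
#' @slot nCnes,nOverlapping CNE counts (all / transposon-overlapping).
#' @slot overlappedBp total CNE bases covered by qualifying transposons.
#' @slot classBp named numeric, overlapped bases per repeat class.
#' @slot cneBases total bases in the CNE set.
#' @slot minOverlap the per-feature overlap threshold used.
#' @name TransposonOverlapReport-class
#' @aliases TransposonOverlapReport
#' @exportClass TransposonOverlapReport
setClass("TransposonOverlapReport", representation(
  nCnes = "integer", nOverlapping = "integer", overlappedBp = "numeric",
  classBp = "numeric", cneBases = "numeric", minOverlap = "integer"
))

setValidity("TransposonOverlapReport", function(object) {
  msg <- character()
  if (object@nOverlapping > object@nCnes)
    msg <- c(msg, "nOverlapping exceeds nCnes")
  if (object@overlappedBp > object@cneBases)
    msg <- c(msg, "overlappedBp exceeds cneBases")
  if (length(msg)) msg else TRUE
})
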