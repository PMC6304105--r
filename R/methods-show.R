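#' @importFrom S4Vectors DataFrame
NULL

## accessors ------------------------------------------------------------

#' @rdname report-accessors
#' @export
setMethod("nTotal", "CompletenessReport", function(x) x@nTotal)
#' @rdname report-accessors
#' @export
setMethod("nFound", "CompletenessReport", function(x) x@nFound)
#' @rdname report-accessors
#' @export
setMethod("foundIds", "CompletenessReport", function(x) x@foundIds)
#' @rdname report-accessors
#' @export
setMethod("missingIds", "CompletenessReport", function(x) x@missingIds)
#' @rdname report-accessors
#' @export
setMethod("bestHits", "CompletenessReport", function(x) x@hits)

#' @rdname report-accessors
#' @export
setMethod("nPairs", "ContiguityReport", function(x) x@nPairs)
#' @rdname report-accessors
#' @export
setMethod("nRecovered", "ContiguityReport", function(x) x@nRecovered)
#' @rdname report-accessors
#' @export
setMethod("recoveredFraction", "ContiguityReport", function(x) x@fraction)
#' @rdname report-accessors
#' @export
setMethod("pairDetail", "ContiguityReport", function(x) x@detail)

#' @rdname report-accessors
#' @export
setMethod("totalBases", "AssemblyReport", function(x) x@totalBases)
#' @rdname report-accessors
#' @export
setMethod("gapBases", "AssemblyReport", function(x) x@gapBases)
#' @rdname report-accessors
#' @export
setMethod("scaffoldNx", "AssemblyReport", function(x) x@scaffoldNx)
#' @rdname report-accessors
#' @export
setMethod("contigNx", "AssemblyReport", function(x) x@contigNx)
#' @rdname report-accessors
#' @export
setMethod("maskedFractionOf", "AssemblyReport", function(x) x@maskedFraction)

#' @rdname report-accessors
#' @export
setMethod("columnCounts", "ColumnPairStats", function(x)
  c(columns = x@columns, match = x@match, mismatch = x@mismatch,
    ins = x@ins, del = x@del, refBases = x@refBases))
#' @rdname report-accessors
#' @export
setMethod("percentBreakdown", "ColumnPairStats", function(x) x@percentages)

#' @rdname report-accessors
#' @export
setMethod("classBases", "TransposonOverlapReport", function(x) x@classBp)
#' @rdname report-accessors
#' @export
setMethod("overlappedBases", "TransposonOverlapReport", function(x) x@overlappedBp)
#' @rdname report-accessors
#' @export
setMethod("nOverlapping", "TransposonOverlapReport", function(x) x@nOverlapping)
#' @rdname report-accessors
#' @export
setMethod("nTotal", "TransposonOverlapReport", function(x) x@nCnes)

#' @rdname mafblock-accessors
#' @export
setMethod("mafSpecies", "MafBlock", function(x) sub("\\..*$", "", x@src))
#' @rdname mafblock-accessors
#' @export
setMethod("mafText", "MafBlock", function(x) setNames(x@text, x@src))
#' @rdname mafblock-accessors
#' @export
setMethod("mafRow", "MafBlock", function(x, species) {
  i <- which(sub("\\..*$", "", x@src) == species)
  if (length(i) == 0L) NA_integer_ else i[1L]
})

## show methods ---------------------------------------------------------

.fmtBp <- function(x) {
  if (x >= 1e6) sprintf("%.1f Mb", x / 1e6)
  else if (x >= 1e3) sprintf("%.1f Kb", x / 1e3)
  else sprintf("%d bp", as.integer(x))
}

setMethod("show", "AssemblyReport", function(object) {
  cat("AssemblyReport\n")
  cat(sprintf("  total: %s in %d scaffold(s), %d contig(s)\n",
              .fmtBp(object@totalBases), object@nScaffolds, object@nContigs))
  cat(sprintf("  gaps (runs of >=%d N): %s (%.2f%%)\n", object@minGapRun,
              .fmtBp(object@gapBases),
              100 * object@gapBases / max(1, object@totalBases)))
  cat(sprintf("  scaffold N50/N90: %s / %s\n",
              .fmtBp(object@scaffoldNx[["50"]]), .fmtBp(object@scaffoldNx[["90"]])))
  cat(sprintf("  contig   N50/N90: %s / %s\n",
              .fmtBp(object@contigNx[["50"]]), .fmtBp(object@contigNx[["90"]])))
  cat(sprintf("  soft-masked: %.1f%%\n", 100 * object@maskedFraction))
})

setMethod("show", "MafBlock", function(object) {
  cat(sprintf("MafBlock with %d row(s), %d column(s); reference: %s\n",
              length(object@src), nchar(object@text[1L]), object@src[1L]))
  for (i in seq_along(object@src)) {
    txt <- object@text[i]
    if (nchar(txt) > 50) txt <- paste0(substr(txt, 1, 47), "...")
    cat(sprintf("  s %-20s %9d %6d %s %9d %s\n", object@src[i], object@start[i],
                object@size[i], object@strand[i], object@srcSize[i], txt))
  }
})

setMethod("show", "ColumnPairStats", function(object) {
  cat(sprintf("ColumnPairStats: %d columns over %d reference bases\n",
              object@columns, object@refBases))
  p <- object@percentages
  cat(sprintf("  match %s%%  substitution %s%%  insertion %s%%  deletion %s%%\n",
              format(p[["match"]]), format(p[["substitution"]]),
              format(p[["insertion"]]), format(p[["deletion"]])))
})

setMethod("show", "CompletenessReport", function(object) {
  cat(sprintf("CompletenessReport: %d of %d elements found (%.1f%%)\n",
              object@nFound, object@nTotal,
              100 * object@nFound / max(1, object@nTotal)))
  if (length(object@missingIds))
    cat("  missing:", paste(utils::head(object@missingIds, 5), collapse = ", "),
        if (length(object@missingIds) > 5) "..." else "", "\n")
})

setMethod("show", "ContiguityReport", function(object) {
  cat(sprintf("ContiguityReport: %d of %d conserved pairs recovered (%s%%)\n",
              object@nRecovered, object@nPairs,
              format(percentOf(object@nRecovered, max(1L, object@nPairs)))))
  st <- table(factor(object@detail$status,
                     levels = c("recovered", "split", "unmapped")))
  cat(sprintf("  recovered %d, split %d, unmapped %d\n",
              st[["recovered"]], st[["split"]], st[["unmapped"]]))
})

setMethod("show", "TransposonOverlapReport", function(object) {
  cat(sprintf("TransposonOverlapReport: %d of %d CNEs overlap a transposon by >=%d bp (%s%%)\n",
              object@nOverlapping, object@nCnes, object@minOverlap,
              format(percentOf(object@nOverlapping, max(1L, object@nCnes)))))
  cat(sprintf("  overlapped: %s of %s CNE bases (%s%%)\n",
              .fmtBp(object@overlappedBp), .fmtBp(object@cneBases),
              format(percentOf(object@overlappedBp, max(1, object@cneBases)))))
  if (sum(object@classBp) > 0) {
    shares <- 100 * object@classBp / sum(object@classBp)
    cat("  class share:",
        paste(sprintf("%s %.0f%%", names(shares), shares), collapse = ", "), "\n")
  }
})
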