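#' Accessors for report objects
#'
#' Small accessor generics for the report classes; slots are never accessed
#' directly by user code.
#'
#' @param x a report object.
#' @return the requested component.
#' @name report-accessors
NULL

#' @rdname report-accessors
#' @export
setGeneric("nTotal", function(x) standardGeneric("nTotal"))
#' @rdname report-accessors
#' @export
setGeneric("nFound", function(x) standardGeneric("nFound"))
#' @rdname report-accessors
#' @export
setGeneric("foundIds", function(x) standardGeneric("foundIds"))
#' @rdname report-accessors
#' @export
setGeneric("missingIds", function(x) standardGeneric("missingIds"))
#' @rdname report-accessors
#' @export
setGeneric("bestHits", function(x) standardGeneric("bestHits"))
#' @rdname report-accessors
#' @export
setGeneric("nPairs", function(x) standardGeneric("nPairs"))
#' @rdname report-accessors
#' @export
setGeneric("nRecovered", function(x) standardGeneric("nRecovered"))
#' @rdname report-accessors
#' @export
setGeneric("recoveredFraction", function(x) standardGeneric("recoveredFraction"))
#' @rdname report-accessors
#' @export
setGeneric("pairDetail", function(x) standardGeneric("pairDetail"))
#' @rdname report-accessors
#' @export
setGeneric("totalBases", function(x) standardGeneric("totalBases"))
#' @rdname report-accessors
#' @export
setGeneric("gapBases", function(x) standardGeneric("gapBases"))
#' @rdname report-accessors
#' @export
setGeneric("scaffoldNx", function(x) standardGeneric("scaffoldNx"))
#' @rdname report-accessors
#' @export
setGeneric("contigNx", function(x) standardGeneric("contigNx"))
#' @rdname report-accessors
#' @export
setGeneric("maskedFractionOf", function(x) standardGeneric("maskedFractionOf"))
#' @rdname report-accessors
#' @export
setGeneric("columnCounts", function(x) standardGeneric("columnCounts"))
#' @rdname report-accessors
#' @export
setGeneric("percentBreakdown", function(x) standardGeneric("percentBreakdown"))
#' @rdname report-accessors
#' @export
setGeneric("classBases", function(x) standardGeneric("classBases"))
#' @rdname report-accessors
#' @export
setGeneric("overlappedBases", function(x) standardGeneric("overlappedBases"))
#' @rdname report-accessors
#' @export
setGeneric("nOverlapping", function(x) standardGeneric("nOverlapping"))

#' MafBlock accessors
#'
#' @param x a [MafBlock-class] object.
#' @param species character, species prefix of a row source name.
#' @return `mafSpecies` returns the species prefixes of all rows;
#'   `mafRow` the row index for a species; `mafText` the aligned texts.
#' @name mafblock-accessors
NULL

#' @rdname mafblock-accessors
#' @export
setGeneric("mafSpecies", function(x) standardGeneric("mafSpecies"))
#' @rdname mafblock-accessors
#' @export
setGeneric("mafText", function(x) standardGeneric("mafText"))
#' @rdname mafblock-accessors
#' @export
setGeneric("mafRow", function(x, species) standardGeneric("mafRow"))
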