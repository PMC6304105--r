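## Alignment hits are modeled as a GRanges on the *target* assembly with
## metadata columns:
##   query_id, query_len, qstart, qend   (1-based closed, original query strand)
##   matches, mismatches                 (aligned columns with both bases)
##   query_gaps   gap columns in the query row  (bases only in the target; cigar D)
##   target_gaps  gap columns in the target row (bases only in the query; cigar I)

.HIT_MCOLS <- c("query_id", "query_len", "qstart", "qend",
                "matches", "mismatches", "query_gaps", "target_gaps")

.splitCigar <- function(cg) {
  m <- gregexpr("[0-9]+[MIDNSHP=X]", cg)[[1L]]
  if (m[1L] == -1L || sum(attr(m, "match.length")) != nchar(cg)) return(NULL)
  ops <- regmatches(cg, gregexpr("[0-9]+[MIDNSHP=X]", cg))[[1L]]
  list(len = as.integer(sub("[MIDNSHP=X]$", "", ops)),
       op = sub("^[0-9]+", "", ops))
}

#' Read element-to-assembly alignments from PAF
#'
#' Parses a PAF file (12 standard columns plus tags) into the internal hit
#' representation: a `GRanges` on the target assembly with per-hit query
#' span, match/mismatch and gap-base accounting. A `cg:Z:` cigar tag is
#' required on every line so that identity can be recomputed: match columns
#' come from the residue-match column (column 10), mismatches from the
#' cigar's aligned columns minus the matches, and the two gap totals from
#' the `D` (base only in target) and `I` (base only in query) operations.
#'
#' @param path path to a PAF file.
#' @return a `GRanges` of hits (see package vignette for the column model).
#' @details Lines whose cigar-implied spans contradict the stated query or
#'   target spans are rejected with the offending line number, as are lines
#'   without a cigar.
#' @export
readPaf <- function(path) {
  if (!file.exists(path)) stop("cannot read PAF file: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(.emptyHits())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  parseLine <- function(i) {
    f <- fields[[i]]
    if (length(f) < 12L)
      stop("PAF line ", i, ": fewer than 12 columns", call. = FALSE)
    cg <- grep("^cg:Z:", f[-(1:12)], value = TRUE)
    if (length(cg) != 1L)
      stop("PAF line ", i, ": missing cg cigar tag", call. = FALSE)
    cig <- .splitCigar(sub("^cg:Z:", "", cg))
    if (is.null(cig))
      stop("PAF line ", i, ": malformed cigar", call. = FALSE)
    qlen <- as.numeric(f[2]); qs <- as.numeric(f[3]); qe <- as.numeric(f[4])
    ts <- as.numeric(f[8]); te <- as.numeric(f[9]); nmatch <- as.numeric(f[10])
    alnM <- sum(cig$len[cig$op %in% c("M", "=", "X")])
    insQ <- sum(cig$len[cig$op == "I"])   # bases only in query
    delQ <- sum(cig$len[cig$op == "D"])   # bases only in target
    if (alnM + insQ != qe - qs)
      stop("PAF line ", i, ": cigar-implied query span (", alnM + insQ,
           ") differs from stated span (", qe - qs, ")", call. = FALSE)
    if (alnM + delQ != te - ts)
      stop("PAF line ", i, ": cigar-implied target span (", alnM + delQ,
           ") differs from stated span (", te - ts, ")", call. = FALSE)
    if (nmatch > alnM)
      stop("PAF line ", i, ": residue matches exceed aligned columns", call. = FALSE)
    list(qid = f[1], qlen = qlen, qs = qs + 1, qe = qe,
         strand = f[5], tname = f[6], tlen = as.numeric(f[7]),
         ts = ts + 1, te = te, matches = nmatch,
         mismatches = alnM - nmatch, qgaps = delQ, tgaps = insQ)
  }
  rows <- lapply(seq_along(fields), parseLine)
  g <- function(k) vapply(rows, `[[`, rows[[1L]][[k]], k)
  gr <- GenomicRanges::GRanges(g("tname"), IRanges::IRanges(g("ts"), g("te")),
                               strand = g("strand"))
  gr$query_id <- g("qid"); gr$query_len <- g("qlen")
  gr$qstart <- g("qs"); gr$qend <- g("qe")
  gr$matches <- g("matches"); gr$mismatches <- g("mismatches")
  gr$query_gaps <- g("qgaps"); gr$target_gaps <- g("tgaps")
  tl <- tapply(g("tlen"), g("tname"), max)
  GenomeInfoDb::seqlengths(gr) <- as.integer(tl[GenomeInfoDb::seqlevels(gr)])
  gr
}

.emptyHits <- function() {
  gr <- GenomicRanges::GRanges()
  for (m in .HIT_MCOLS)
    S4Vectors::mcols(gr)[[m]] <- if (m == "query_id") character() else numeric()
  gr
}

#' Write alignment hits as PAF
#'
#' Emits one PAF line per hit with a canonical `cg:Z:` cigar of the form
#' `{matches}={mismatches}X{target_gaps}I{query_gaps}D` (zero-length
#' operations omitted). Column-level mismatch positions are not retained by
#' the hit model, so the cigar is canonical rather than positional; parsing
#' the output back recovers every hit field exactly.
#'
#' @param hits a hit `GRanges` (see [readPaf()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writePaf <- function(hits, path) {
  if (length(hits) == 0L) { writeLines(character(), path); return(invisible(path)) }
  sl <- GenomeInfoDb::seqlengths(hits)
  tname <- as.character(GenomicRanges::seqnames(hits))
  tlen <- sl[tname]
  tlen[is.na(tlen)] <- GenomicRanges::end(hits)[is.na(tlen)]
  cig <- sprintf("%s%s%s%s",
    ifelse(hits$matches > 0, paste0(hits$matches, "="), ""),
    ifelse(hits$mismatches > 0, paste0(hits$mismatches, "X"), ""),
    ifelse(hits$target_gaps > 0, paste0(hits$target_gaps, "I"), ""),
    ifelse(hits$query_gaps > 0, paste0(hits$query_gaps, "D"), ""))
  blockLen <- hits$matches + hits$mismatches + hits$query_gaps + hits$target_gaps
  strand <- as.character(GenomicRanges::strand(hits))
  strand[strand == "*"] <- "+"
  out <- paste(hits$query_id, format(hits$query_len, scientific = FALSE, trim = TRUE),
               hits$qstart - 1, hits$qend, strand,
               tname, format(tlen, scientific = FALSE, trim = TRUE),
               GenomicRanges::start(hits) - 1, GenomicRanges::end(hits),
               hits$matches, blockLen, 255,
               paste0("cg:Z:", cig), sep = "\t")
  writeLines(out, path)
  invisible(path)
}

#' Alignment identity and coverage of hits
#'
#' `hitIdentity` is the fraction of matching columns; under the default
#' `"gap-inclusive"` mode the denominator counts gap columns
#' (`matches / (matches + mismatches + query_gaps + target_gaps)`), under
#' `"gap-exclusive"` only columns with a base on both sides
#' (`matches / (matches + mismatches)`). `hitCoverage` is query-side only:
#' the fraction of the element length that is aligned.
#'
#' @param hits a hit `GRanges`.
#' @param mode identity denominator convention.
#' @return numeric vector in \[0, 1\], one value per hit.
#' @export
hitIdentity <- function(hits, mode = c("gap-inclusive", "gap-exclusive")) {
  mode <- match.arg(mode)
  aln <- hits$matches + hits$mismatches
  if (any(aln == 0))
    stop("hit with no aligned bases", call. = FALSE)
  den <- if (mode == "gap-inclusive")
    aln + hits$query_gaps + hits$target_gaps else aln
  as.numeric(hits$matches / den)
}

#' @rdname hitIdentity
#' @export
hitCoverage <- function(hits) {
  if (any(hits$query_len <= 0)) stop("zero-length query", call. = FALSE)
  as.numeric((hits$qend - hits$qstart + 1) / hits$query_len)
}
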