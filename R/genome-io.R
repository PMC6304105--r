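#' Read a genome or element FASTA
#'
#' Reads a (multi-)FASTA into a [Biostrings::BStringSet]. A `BStringSet` is
#' used rather than a `DNAStringSet` so that soft-masking case is preserved
#' exactly: lowercase bases mark repeat-annotated sequence and are counted by
#' [maskedFraction()], but are treated as ordinary nucleotides everywhere
#' else.
#'
#' @param path path to a FASTA file (multi-line records allowed).
#' @return a `BStringSet`, records in file order, names set to FASTA ids.
#' @details Record ids must be unique and sequences non-empty and restricted
#'   to the alphabet `{A,C,G,T,N}` in either case; violations are errors.
#' @export
readGenome <- function(path) {
  if (!file.exists(path)) stop("cannot read FASTA file: ", path, call. = FALSE)
  x <- Biostrings::readBStringSet(path)
  if (length(x) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  # FASTA ids = first whitespace-separated token of the header
  names(x) <- sub("\\s.*$", "", names(x))
  dup <- unique(names(x)[duplicated(names(x))])
  if (length(dup))
    stop("duplicate FASTA id(s): ", paste(dup, collapse = ", "), call. = FALSE)
  if (any(!nzchar(names(x)))) stop("FASTA record with empty id", call. = FALSE)
  if (any(Biostrings::width(x) < 1L))
    stop("FASTA record with empty sequence", call. = FALSE)
  bad <- Biostrings::width(x) -
    rowSums(Biostrings::letterFrequency(x, c("Aa", "Cc", "Gg", "Tt", "Nn")))
  if (any(bad > 0))
    stop("non-ACGTN characters in record(s): ",
         paste(names(x)[bad > 0], collapse = ", "), call. = FALSE)
  x
}

#' Write sequences to FASTA
#'
#' @param x a named `BStringSet` (or coercible character vector).
#' @param path output path.
#' @param width line width for wrapping (default 70).
#' @return `path`, invisibly.
#' @export
writeGenome <- function(x, path, width = 70L) {
  if (is.character(x)) x <- Biostrings::BStringSet(x)
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

#' Read a BED file into a GRanges
#'
#' Parses BED3+ (tab-separated, 0-based half-open per the BED convention)
#' into a sorted [GenomicRanges::GRanges]. Column 4 becomes `name`, column 5
#' `score`, column 6 the strand; further columns are retained as `extra1`,
#' `extra2`, ... metadata columns.
#'
#' Validation is strict: non-integer coordinates and empty or inverted
#' intervals (`start >= end`) are errors that report the offending line
#' number.
#'
#' @param path path to a BED file (no header).
#' @return a `GRanges`, sorted by (seqnames, start, end), 1-based closed
#'   coordinates as usual for `GRanges`.
#' @export
readBed <- function(path) {
  if (!file.exists(path)) stop("cannot read BED file: ", path, call. = FALSE)
  lines <- readLines(path)
  keep <- nzchar(lines) & !startsWith(lines, "#") & !startsWith(lines, "track")
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L)
    return(GenomicRanges::GRanges())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L))
    stop("BED line ", lineno[which(nf < 3L)[1L]], ": fewer than 3 columns",
         call. = FALSE)
  chrom <- vapply(fields, `[[`, "", 1L)
  s <- vapply(fields, `[[`, "", 2L)
  e <- vapply(fields, `[[`, "", 3L)
  badint <- !grepl("^[0-9]+$", s) | !grepl("^[0-9]+$", e)
  if (any(badint))
    stop("BED line ", lineno[which(badint)[1L]], ": non-integer coordinate",
         call. = FALSE)
  start0 <- as.numeric(s); end <- as.numeric(e)
  bad <- start0 >= end
  if (any(bad))
    stop("BED line ", lineno[which(bad)[1L]], ": start >= end", call. = FALSE)
  strand <- rep("*", length(lines))
  if (any(nf >= 6L)) {
    s6 <- vapply(fields, function(f) if (length(f) >= 6L) f[[6L]] else "*", "")
    strand <- ifelse(s6 %in% c("+", "-"), s6, "*")
  }
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start0 + 1, end),
                               strand = strand)
  if (any(nf >= 4L))
    gr$name <- vapply(fields, function(f) if (length(f) >= 4L) f[[4L]] else NA_character_, "")
  if (any(nf >= 5L))
    gr$score <- vapply(fields, function(f) if (length(f) >= 5L) f[[5L]] else NA_character_, "")
  maxf <- max(nf)
  if (maxf > 6L) for (j in 7L:maxf) {
    S4Vectors::mcols(gr)[[paste0("extra", j - 6L)]] <-
      vapply(fields, function(f) if (length(f) >= j) f[[j]] else NA_character_, "")
  }
  GenomeInfoDb::seqlevels(gr) <- sort(GenomeInfoDb::seqlevels(gr))
  GenomicRanges::sort(gr, ignore.strand = TRUE)
}

#' Write a GRanges to BED
#'
#' Writes BED3/BED6 (tab-separated, 0-based half-open). `name` and `score`
#' metadata columns and strand are emitted when present; strand `"*"` is
#' written as `"."`.
#'
#' @param gr a `GRanges`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeBed <- function(gr, path) {
  n <- length(gr)
  cols <- list(as.character(GenomicRanges::seqnames(gr)),
               format(GenomicRanges::start(gr) - 1, scientific = FALSE, trim = TRUE),
               format(GenomicRanges::end(gr), scientific = FALSE, trim = TRUE))
  hasName <- "name" %in% names(S4Vectors::mcols(gr))
  strnd <- as.character(GenomicRanges::strand(gr))
  hasStrand <- any(strnd != "*")
  if (hasName || hasStrand) {
    cols[[4L]] <- if (hasName) as.character(gr$name) else rep(".", n)
    cols[[5L]] <- if ("score" %in% names(S4Vectors::mcols(gr)))
      as.character(gr$score) else rep("0", n)
    cols[[6L]] <- ifelse(strnd == "*", ".", strnd)
  }
  writeLines(do.call(paste, c(cols, sep = "\t")), path)
  invisible(path)
}
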