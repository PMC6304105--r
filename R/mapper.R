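#' Map elements to an assembly by exact-seed ungapped extension
#'
#' A small built-in mapper for conserved-element sequences: each element is
#' anchored by exact `seedLen`-mer matches (both strands) and every anchored
#' placement is scored by ungapped column-wise comparison over the full
#' element length, clipped at scaffold boundaries. An element planted
#' verbatim in the assembly is guaranteed a hit with identity and coverage
#' 1.0. The mapper is ungapped by design; element divergence is expected to
#' be substitution-dominated at the scales it is used for.
#'
#' @param elements named `BStringSet` of element sequences.
#' @param assembly named `BStringSet` of scaffolds.
#' @param seedLen exact-match seed length (default 12); every element must
#'   be at least this long.
#' @return a hit `GRanges` (same column model as [readPaf()]); elements
#'   with no seed match produce no hit.
#' @export
mapElements <- function(elements, assembly, seedLen = 12L) {
  seedLen <- .assertCount(seedLen, "seedLen", min = 4)
  if (any(Biostrings::width(elements) < seedLen))
    stop("every element must be at least seedLen long", call. = FALSE)
  scafs <- toupper(as.character(assembly))
  scafInts <- lapply(scafs, utf8ToInt)
  nInt <- utf8ToInt("N")
  out <- list()
  for (ei in seq_along(elements)) {
    qid <- names(elements)[ei]
    fwd <- toupper(as.character(elements[[ei]]))
    len <- nchar(fwd)
    for (strand in c("+", "-")) {
      qseq <- if (strand == "+") fwd else .revComp(fwd)
      qInt <- utf8ToInt(qseq)
      seedOffs <- unique(c(seq(1L, len - seedLen + 1L, by = seedLen),
                           len - seedLen + 1L))
      for (si in seq_along(scafs)) {
        slen <- nchar(scafs[si])
        offs <- integer()
        for (so in seedOffs) {
          m <- gregexpr(substr(qseq, so, so + seedLen - 1L), scafs[si],
                        fixed = TRUE)[[1L]]
          if (m[1L] != -1L) offs <- c(offs, as.integer(m) - so + 1L)
        }
        for (off in unique(offs)) {
          ts <- max(1L, off); te <- min(slen, off + len - 1L)
          alen <- te - ts + 1L
          if (alen < seedLen) next
          qa <- ts - off + 1L; qb <- te - off + 1L
          a <- qInt[qa:qb]
          b <- scafInts[[si]][ts:te]
          matches <- sum(a == b & a != nInt)
          if (matches < seedLen) next
          qs <- if (strand == "+") qa else len - qb + 1L
          qe <- if (strand == "+") qb else len - qa + 1L
          out[[length(out) + 1L]] <- list(
            qid = qid, qlen = len, qs = qs, qe = qe, strand = strand,
            tname = names(scafs)[si], ts = ts, te = te,
            matches = matches, mismatches = alen - matches)
        }
      }
    }
  }
  if (length(out) == 0L) {
    gr <- .emptyHits()
    GenomeInfoDb::seqlevels(gr) <- names(assembly)
    GenomeInfoDb::seqlengths(gr) <- Biostrings::width(assembly)
    return(gr)
  }
  g <- function(k) vapply(out, `[[`, out[[1L]][[k]], k)
  gr <- GenomicRanges::GRanges(g("tname"), IRanges::IRanges(g("ts"), g("te")),
                               strand = g("strand"))
  gr$query_id <- g("qid"); gr$query_len <- as.numeric(g("qlen"))
  gr$qstart <- as.numeric(g("qs")); gr$qend <- as.numeric(g("qe"))
  gr$matches <- as.numeric(g("matches")); gr$mismatches <- as.numeric(g("mismatches"))
  gr$query_gaps <- 0; gr$target_gaps <- 0
  GenomeInfoDb::seqlevels(gr) <- names(assembly)
  GenomeInfoDb::seqlengths(gr) <- Biostrings::width(assembly)
  gr
}

.revComp <- function(x) {
  paste(rev(strsplit(chartr("ACGTNacgtn", "TGCANtgcan", x), "")[[1L]]),
        collapse = "")
}
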