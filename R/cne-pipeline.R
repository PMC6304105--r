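#' Merge two conserved-region call sets
#'
#' Unions the two sets of conserved-region calls (typically from two
#' independent constraint callers, e.g. a PhastCons-style and a GERP-style
#' scan), joins regions separated by at most `joinGap` bases, and drops
#' merged regions shorter than `minLen`. Each surviving region records
#' which input set(s) contributed to it.
#'
#' @param setA,setB `GRanges` of conserved-region calls on one reference.
#' @param joinGap regions separated by at most this many bases are joined
#'   (default 10).
#' @param minLen minimum merged region length (default 30).
#' @return a `GRanges` with metadata columns `source` ("setA", "setB" or
#'   "setA,setB") and `region_id`.
#' @export
mergeConservedSets <- function(setA, setB, joinGap = 10L, minLen = 30L) {
  minLen <- .assertCount(minLen, "minLen", min = 1)
  merged <- mergeIntervals(c(GenomicRanges::granges(setA),
                             GenomicRanges::granges(setB)), joinGap)
  merged <- merged[GenomicRanges::width(merged) >= minLen]
  fromA <- IRanges::overlapsAny(merged, setA, ignore.strand = TRUE)
  fromB <- IRanges::overlapsAny(merged, setB, ignore.strand = TRUE)
  merged$source <- paste0(ifelse(fromA, "setA", ""),
                          ifelse(fromA & fromB, ",", ""),
                          ifelse(fromB, "setB", ""))
  merged$region_id <- sprintf("region_%05d", seq_along(merged))
  merged
}

#' Per-species alignment-support windows from a MAF
#'
#' For every non-reference species, finds the reference-genome intervals
#' where that species aligns well: every run of `win` consecutive alignment
#' columns (columns where the reference has a base) with pairwise identity
#' at least `minId` marks its reference positions; marked positions are
#' merged into maximal intervals and only intervals of at least `win` bp
#' are reported. These windows are the evidence unit for species support
#' and lineage classification.
#'
#' @param maf list of [MafBlock-class] (see [readMaf()]).
#' @param refSpecies species prefix of the reference rows; every block must
#'   contain it.
#' @param win window size in columns and minimum reported interval length
#'   (default 30).
#' @param minId minimum window identity (default 0.60).
#' @param identityMode `"gap-inclusive"` (default): a species gap column
#'   counts as a non-match over a denominator of `win` columns;
#'   `"gap-exclusive"`: gap columns are dropped from the denominator.
#' @return a `GRanges` on the reference with a `species` metadata column,
#'   merged per species.
#' @export
computeSupportWindows <- function(maf, refSpecies, win = 30L, minId = 0.60,
                                  identityMode = c("gap-inclusive", "gap-exclusive")) {
  identityMode <- match.arg(identityMode)
  win <- .assertCount(win, "win", min = 1)
  minId <- .assertFraction(minId, "minId")
  perSpecies <- list()  # species -> list of (chrom, positions IRanges)
  for (bi in seq_along(maf)) {
    b <- maf[[bi]]
    sp <- sub("\\..*$", "", b@src)
    refRow <- which(sp == refSpecies)[1L]
    if (is.na(refRow))
      stop("reference species '", refSpecies, "' missing from MAF block ", bi,
           call. = FALSE)
    refChrom <- sub("^[^.]*\\.", "", b@src[refRow])
    refChars <- strsplit(toupper(b@text[refRow]), "")[[1L]]
    refPos <- .mafRefPositions(b, refRow)
    keepCol <- refChars != "-"   # columns where the reference has a base
    rp <- refPos[keepCol]
    rc <- refChars[keepCol]
    nc <- length(rc)
    if (nc < win) next
    for (ri in seq_along(b@src)[-refRow]) {
      qc <- strsplit(toupper(b@text[ri]), "")[[1L]][keepCol]
      isMatch <- qc == rc & qc != "-"
      csM <- c(0, cumsum(isMatch))
      starts <- seq_len(nc - win + 1L)
      m <- csM[starts + win] - csM[starts]
      ok <- if (identityMode == "gap-inclusive") {
        m / win >= minId
      } else {
        csG <- c(0, cumsum(qc != "-"))
        den <- csG[starts + win] - csG[starts]
        den > 0 & m / den >= minId
      }
      if (!any(ok)) next
      # mark columns of qualifying windows via a difference array
      mark <- integer(nc + 1L)
      mark[starts[ok]] <- mark[starts[ok]] + 1L
      mark[starts[ok] + win] <- mark[starts[ok] + win] - 1L
      marked <- cumsum(mark)[seq_len(nc)] > 0L
      ir <- IRanges::reduce(IRanges::IRanges(rp[marked], width = 1L))
      spName <- sp[ri]
      perSpecies[[spName]] <- c(perSpecies[[spName]],
                                list(list(chrom = refChrom, ir = ir)))
    }
  }
  if (length(perSpecies) == 0L) {
    gr <- GenomicRanges::GRanges(); gr$species <- character(); return(gr)
  }
  res <- lapply(names(perSpecies), function(spName) {
    parts <- perSpecies[[spName]]
    gr <- do.call(c, lapply(parts, function(p)
      GenomicRanges::GRanges(p$chrom, p$ir)))
    gr <- GenomicRanges::reduce(gr)
    gr <- gr[GenomicRanges::width(gr) >= win]
    if (length(gr)) gr$species <- spName
    gr
  })
  out <- do.call(c, res[lengths(res) > 0L])
  if (is.null(out)) { out <- GenomicRanges::GRanges(); out$species <- character() }
  GenomicRanges::sort(out, ignore.strand = TRUE)
}

#' Keep conserved regions supported by enough species
#'
#' A conserved region is retained when it overlaps an alignment-support
#' window (by at least `minWindowOverlap` bp) in at least `minSpecies`
#' distinct species. The supporting species of each retained region are
#' recorded.
#'
#' @param regions `GRanges` of conserved regions (see [mergeConservedSets()]).
#' @param windows support windows with a `species` column (see
#'   [computeSupportWindows()]).
#' @param minSpecies minimum number of distinct supporting species
#'   (default 4).
#' @param minWindowOverlap minimum overlap in bp to count a window
#'   (default 1).
#' @return the retained subset of `regions` with added metadata columns
#'   `n_species` and `supporting_species` (comma-separated).
#' @export
speciesSupportFilter <- function(regions, windows, minSpecies = 4L,
                                 minWindowOverlap = 1L) {
  minSpecies <- .assertCount(minSpecies, "minSpecies")
  sup <- .speciesPerRange(regions, windows, minWindowOverlap)
  keep <- lengths(sup) >= minSpecies
  out <- regions[keep]
  out$n_species <- unname(lengths(sup)[keep])
  out$supporting_species <- unname(vapply(sup[keep], paste, "", collapse = ","))
  out
}

.speciesPerRange <- function(query, windows, minOverlap = 1L) {
  hits <- GenomicRanges::findOverlaps(query, windows,
                                      minoverlap = as.integer(minOverlap),
                                      ignore.strand = TRUE)
  sp <- split(windows$species[S4Vectors::subjectHits(hits)],
              factor(S4Vectors::queryHits(hits), levels = seq_along(query)))
  lapply(sp, function(s) sort(unique(s)))
}

#' Derive CNEs by subtracting exons from conserved regions
#'
#' Subtracts exonic bases from the conserved regions and keeps the
#' resulting non-exonic fragments of at least `minLen` bp. Each fragment
#' records the region it derives from.
#'
#' @param regions conserved regions (`GRanges`, non-overlapping, with a
#'   `region_id` column; see [mergeConservedSets()]).
#' @param exons exon annotation (`GRanges`).
#' @param minLen minimum CNE length (default 30).
#' @return a `GRanges` of CNEs with metadata columns `cne_id` and
#'   `parent_region`.
#' @export
deriveCnes <- function(regions, exons, minLen = 30L) {
  minLen <- .assertCount(minLen, "minLen", min = 1)
  frags <- subtractIntervals(regions, exons)
  frags <- frags[GenomicRanges::width(frags) >= minLen]
  ov <- GenomicRanges::findOverlaps(frags, regions, ignore.strand = TRUE,
                                    select = "first")
  frags$cne_id <- sprintf("cne_%06d", seq_along(frags))
  frags$parent_region <- if (!is.null(regions$region_id))
    regions$region_id[ov] else as.character(ov)
  frags
}

#' Classify CNEs by lineage specificity
#'
#' Classifies each CNE from its per-species alignment-support windows:
#' `ingroup_specific` when at least `minIngroup` ingroup species overlap
#' the CNE and not a single outgroup species does; `shared` when at least
#' `minIngroup` ingroup species and at least one outgroup species overlap;
#' `unclassified` otherwise. The three classes are mutually exclusive and
#' exhaustive.
#'
#' @param cnes `GRanges` of CNEs.
#' @param windows support windows with a `species` column.
#' @param ingroup,outgroup disjoint character vectors of species names;
#'   every species occurring in `windows` must be declared in one of them.
#' @param minIngroup minimum ingroup species overlapping (default 6).
#' @param minWindowOverlap minimum overlap in bp to count a window
#'   (default 1).
#' @return `cnes` with added metadata columns `lineage_class`,
#'   `n_ingroup`, `n_outgroup`.
#' @export
classifyLineage <- function(cnes, windows, ingroup, outgroup, minIngroup = 6L,
                            minWindowOverlap = 1L) {
  minIngroup <- .assertCount(minIngroup, "minIngroup")
  if (length(intersect(ingroup, outgroup)))
    stop("ingroup and outgroup must be disjoint", call. = FALSE)
  undecl <- setdiff(unique(windows$species), c(ingroup, outgroup))
  if (length(undecl))
    stop("species in windows not declared ingroup/outgroup: ",
         paste(undecl, collapse = ", "), call. = FALSE)
  sup <- .speciesPerRange(cnes, windows, minWindowOverlap)
  nIn <- unname(vapply(sup, function(s) sum(s %in% ingroup), 0L))
  nOut <- unname(vapply(sup, function(s) sum(s %in% outgroup), 0L))
  cls <- ifelse(nIn >= minIngroup & nOut == 0L, "ingroup_specific",
         ifelse(nIn >= minIngroup & nOut >= 1L, "shared", "unclassified"))
  cnes$lineage_class <- cls
  cnes$n_ingroup <- nIn
  cnes$n_outgroup <- nOut
  cnes
}

#' Read a RepeatMasker .out annotation
#'
#' Parses the standard RepeatMasker `.out` table (three header lines,
#' whitespace-separated columns, query coordinates 1-based inclusive) into
#' a `GRanges` with normalized repeat classes: the class is the part of the
#' class/family column before `/`, with any `?` qualifiers stripped;
#' classes other than SINE, LINE, LTR and DNA are normalized to `other`.
#'
#' @param path path to a `.out` file.
#' @return a `GRanges` with metadata columns `repeat_class`, `family` and
#'   `repeat_name`.
#' @export
readRepeatMaskerOut <- function(path) {
  if (!file.exists(path)) stop("cannot read RepeatMasker file: ", path,
                               call. = FALSE)
  lines <- readLines(path)
  if (length(lines) > 3L) lines <- lines[-(1:3)] else lines <- character()
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    gr <- GenomicRanges::GRanges()
    gr$repeat_class <- character(); gr$family <- character()
    gr$repeat_name <- character()
    return(gr)
  }
  fields <- strsplit(trimws(lines), "[ \t]+")
  n <- length(fields)
  parse1 <- function(i) {
    f <- fields[[i]]
    if (length(f) < 11L)
      stop(".out line ", i + 3L, ": fewer than 11 columns", call. = FALSE)
    if (!grepl("^[0-9]+$", f[6]) || !grepl("^[0-9]+$", f[7]))
      stop(".out line ", i + 3L, ": malformed coordinate", call. = FALSE)
    b <- as.numeric(f[6]); e <- as.numeric(f[7])
    if (b > e) stop(".out line ", i + 3L, ": begin > end", call. = FALSE)
    list(chrom = f[5], start = b, end = e, name = f[10], classfam = f[11])
  }
  rows <- lapply(seq_len(n), parse1)
  classfam <- gsub("?", "", vapply(rows, `[[`, "", "classfam"), fixed = TRUE)
  cls <- sub("/.*$", "", classfam)
  cls[!cls %in% c("SINE", "LINE", "LTR", "DNA")] <- "other"
  fam <- ifelse(grepl("/", classfam), sub("^[^/]*/", "", classfam), "")
  gr <- GenomicRanges::GRanges(
    vapply(rows, `[[`, "", "chrom"),
    IRanges::IRanges(vapply(rows, `[[`, 0, "start"),
                     vapply(rows, `[[`, 0, "end")))
  gr$repeat_class <- cls
  gr$family <- fam
  gr$repeat_name <- vapply(rows, `[[`, "", "name")
  gr
}

#' Write repeats in RepeatMasker .out layout
#'
#' Emits the three-line header followed by minimal whitespace-separated
#' rows; only the columns consumed by [readRepeatMaskerOut()] carry
#' information, the rest are placeholders.
#'
#' @param repeats `GRanges` with `repeat_class` (and optionally `family`,
#'   `repeat_name`) metadata columns.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeRepeatMaskerOut <- function(repeats, path) {
  hdr <- c(
    "   SW  perc perc perc  query     position in query        matching repeat       position in repeat",
    "score  div. del. ins.  sequence  begin  end    (left)     repeat     class/family  begin end (left)",
    "")
  fam <- if (!is.null(repeats$family)) repeats$family else rep("", length(repeats))
  classfam <- ifelse(nzchar(fam), paste0(repeats$repeat_class, "/", fam),
                     repeats$repeat_class)
  nm <- if (!is.null(repeats$repeat_name)) repeats$repeat_name
        else paste0("rep", seq_along(repeats))
  rows <- sprintf(" 1000  0.0  0.0  0.0  %s %d %d (0) + %s %s 1 %d (0) %d",
                  as.character(GenomicRanges::seqnames(repeats)),
                  GenomicRanges::start(repeats), GenomicRanges::end(repeats),
                  nm, classfam, GenomicRanges::width(repeats),
                  seq_along(repeats))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Transposon overlap accounting for a CNE set
#'
#' Restricts the repeat annotation to the four transposon classes (SINE,
#' LINE, LTR, DNA) and counts the CNEs that overlap a transposon. By
#' default a CNE qualifies when its overlap with at least one *single*
#' transposon feature is at least `minOverlap` bp; with
#' `sumOverlaps = TRUE` the per-CNE total across features is thresholded
#' instead. For qualifying CNEs the report totals the transposon-covered
#' bases, their per-class breakdown, and the fraction of all CNE bases
#' explained.
#'
#' @param cnes `GRanges` of CNEs.
#' @param repeats `GRanges` with a `repeat_class` column.
#' @param minOverlap minimum overlap in bp (default 30).
#' @param sumOverlaps threshold the per-CNE sum across features instead of
#'   single features (default `FALSE`).
#' @return a [TransposonOverlapReport-class].
#' @export
transposonOverlap <- function(cnes, repeats, minOverlap = 30L,
                              sumOverlaps = FALSE) {
  minOverlap <- .assertCount(minOverlap, "minOverlap", min = 1)
  tp <- repeats[repeats$repeat_class %in% c("SINE", "LINE", "LTR", "DNA")]
  hits <- GenomicRanges::findOverlaps(cnes, tp, ignore.strand = TRUE)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  ow <- GenomicRanges::width(GenomicRanges::pintersect(
    GenomicRanges::granges(cnes)[qh], GenomicRanges::granges(tp)[sh]))
  qualifies <- if (sumOverlaps) {
    tot <- tapply(ow, factor(qh, levels = seq_along(cnes)), sum, default = 0)
    which(tot >= minOverlap)
  } else {
    unique(qh[ow >= minOverlap])
  }
  cneBases <- sum(as.numeric(GenomicRanges::width(cnes)))
  classBp <- setNames(numeric(4), c("SINE", "LINE", "LTR", "DNA"))
  overlappedBp <- 0
  if (length(qualifies)) {
    sel <- qh %in% qualifies
    # union of transposon cover per qualifying CNE, overall and per class
    cover <- GenomicRanges::pintersect(GenomicRanges::granges(cnes)[qh[sel]],
                                       GenomicRanges::granges(tp)[sh[sel]])
    overlappedBp <- coveredBases(cover)
    for (cl in names(classBp)) {
      s <- sel & tp$repeat_class[sh] == cl
      if (any(s))
        classBp[cl] <- coveredBases(GenomicRanges::pintersect(
          GenomicRanges::granges(cnes)[qh[s]], GenomicRanges::granges(tp)[sh[s]]))
    }
  }
  new("TransposonOverlapReport", nCnes = length(cnes),
      nOverlapping = length(qualifies), overlappedBp = overlappedBp,
      classBp = classBp, cneBases = cneBases, minOverlap = minOverlap)
}
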