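#' Configuration for the synthetic clade simulator
#'
#' Builds and validates the parameter set for [simulateClade()]. The
#' defaults describe the desk-scale study system used throughout the test
#' suite: a 200 kb reference genome carrying 50 planted conserved elements,
#' a clade of 9 ingroup species diverged from the reference by independent
#' per-site substitutions at probability 0.05, and 3 outgroup species at
#' probability 0.15 (still comfortably above the 60% identity window
#' threshold where sequence is conserved). Elements are split into
#' ingroup-specific (outgroup loci replaced by unrelated random sequence),
#' shared (conserved in all species), and decoys (conserved in too few
#' ingroup species to pass the species-support filter).
#'
#' @param seed integer master seed; every output file draws from its own
#'   stream derived from (seed, stream name).
#' @param genomeLen reference genome length in bp.
#' @param nElements number of planted elements.
#' @param elementLenRange min/max element length.
#' @param ingroup,outgroup species names (reference excluded).
#' @param ingroupSubProb,outgroupSubProb per-branch substitution
#'   probabilities, recycled over the species lists.
#' @param refSpecies,chrom reference species and chromosome name.
#' @param classFractions named fractions (ingroup_specific, shared, decoy)
#'   summing to 1.
#' @param decoyConservedSpecies number of ingroup species in which decoy
#'   loci remain conserved (must be below the species-support threshold
#'   for decoys to be filtered out; default 2).
#' @param nExons,exonLenRange,exonOverlapCount exon annotation: count,
#'   length range, and how many exons overlap a planted element edge.
#' @param nTransposons,transposonLenRange,transposonOverlapCount transposon
#'   annotation: count, length range, and how many are planted to overlap
#'   an element by at least 30 bp.
#' @param nBreaks,gapLen assembly fragmentation applied to `assembly.fa`
#'   (0 breaks: the assembly equals the reference); `gapLen >= 25` so that
#'   rejoined fragments register as assembly gaps.
#' @return a validated `SimulationConfig` (a classed list).
#' @export
simulationConfig <- function(seed = 42L,
                             genomeLen = 200000L,
                             nElements = 50L,
                             elementLenRange = c(150L, 350L),
                             ingroup = paste0("squamate", 1:9),
                             outgroup = c("human", "mouse", "chicken"),
                             ingroupSubProb = 0.05,
                             outgroupSubProb = 0.15,
                             refSpecies = "tegu",
                             chrom = "chr1",
                             classFractions = c(ingroup_specific = 0.4,
                                                shared = 0.4, decoy = 0.2),
                             decoyConservedSpecies = 2L,
                             nExons = 20L,
                             exonLenRange = c(60L, 200L),
                             exonOverlapCount = 3L,
                             nTransposons = 12L,
                             transposonLenRange = c(80L, 250L),
                             transposonOverlapCount = 4L,
                             nBreaks = 0L,
                             gapLen = 100L) {
  cfg <- list(seed = .assertCount(seed, "seed"),
              genomeLen = .assertCount(genomeLen, "genomeLen", min = 1000),
              nElements = .assertCount(nElements, "nElements", min = 2),
              elementLenRange = as.integer(elementLenRange),
              ingroup = ingroup, outgroup = outgroup,
              ingroupSubProb = rep_len(ingroupSubProb, length(ingroup)),
              outgroupSubProb = rep_len(outgroupSubProb, length(outgroup)),
              refSpecies = refSpecies, chrom = chrom,
              classFractions = classFractions,
              decoyConservedSpecies = .assertCount(decoyConservedSpecies,
                                                   "decoyConservedSpecies"),
              nExons = .assertCount(nExons, "nExons"),
              exonLenRange = as.integer(exonLenRange),
              exonOverlapCount = .assertCount(exonOverlapCount, "exonOverlapCount"),
              nTransposons = .assertCount(nTransposons, "nTransposons"),
              transposonLenRange = as.integer(transposonLenRange),
              transposonOverlapCount = .assertCount(transposonOverlapCount,
                                                    "transposonOverlapCount"),
              nBreaks = .assertCount(nBreaks, "nBreaks"),
              gapLen = .assertCount(gapLen, "gapLen", min = 25))
  sp <- c(cfg$refSpecies, cfg$ingroup, cfg$outgroup)
  if (anyDuplicated(sp)) stop("species names must be unique", call. = FALSE)
  if (any(c(cfg$ingroupSubProb, cfg$outgroupSubProb) < 0) ||
      any(c(cfg$ingroupSubProb, cfg$outgroupSubProb) > 1))
    stop("substitution probabilities must be in [0, 1]", call. = FALSE)
  if (abs(sum(cfg$classFractions) - 1) > 1e-9 ||
      !setequal(names(cfg$classFractions),
                c("ingroup_specific", "shared", "decoy")))
    stop("classFractions must be named ingroup_specific/shared/decoy and sum to 1",
         call. = FALSE)
  # the exon zone at the head of each element slot must hold exons and
  # background transposons; elements live behind it
  cfg$exonZone <- 300L
  slotLen <- cfg$genomeLen %/% cfg$nElements
  if (slotLen < cfg$exonZone + max(cfg$elementLenRange) + 20L)
    stop("element total exceeds genome capacity", call. = FALSE)
  if (max(cfg$exonLenRange) > cfg$exonZone - 10L ||
      max(cfg$transposonLenRange) > cfg$exonZone - 10L)
    stop("exon/transposon lengths exceed the placement zone", call. = FALSE)
  structure(cfg, class = "SimulationConfig")
}

.randSeq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

# substitute each base independently with probability p, uniformly to one
# of the three other bases (Jukes-Cantor style)
.mutate <- function(chars, p) {
  if (p <= 0) return(chars)
  idx <- which(stats::runif(length(chars)) < p)
  if (length(idx) == 0L) return(chars)
  bases <- c("A", "C", "G", "T")
  cur <- match(chars[idx], bases)
  step <- sample.int(3L, length(idx), replace = TRUE)
  chars[idx] <- bases[((cur - 1L + step) %% 4L) + 1L]
  chars
}

#' Simulate a toy clade with planted ground truth
#'
#' Generates a complete, self-consistent input set for every pipeline
#' stage, written to `dir`: the reference genome FASTA, one FASTA per
#' species (substitution-only divergence, so alignment is positional), a
#' reference-anchored MAF with one block per planted element, two
#' conserved-region BED call sets whose union reconstructs the planted
#' elements after gap-joining, an exon BED, a RepeatMasker-style `.out`
#' annotation, per-outgroup element location BEDs, the element FASTA, a
#' fragmented `assembly.fa`, and the truth tables. Identical seeds produce
#' byte-identical files.
#'
#' @param config a [simulationConfig()].
#' @param dir output directory (created if needed).
#' @return invisibly, a list with `dir`, `paths` (named file paths),
#'   `truth` (`elements` and `pairs` data frames) and `config`.
#' @export
simulateClade <- function(config = simulationConfig(), dir = tempfile("clade")) {
  stopifnot(inherits(config, "SimulationConfig"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  P <- function(f) file.path(dir, f)
  cfg <- config
  seed <- cfg$seed

  ## reference genome ---------------------------------------------------
  refChars <- withStream(seed, "genome",
    sample(c("A", "C", "G", "T"), cfg$genomeLen, replace = TRUE))

  ## element placement and classes --------------------------------------
  slotLen <- cfg$genomeLen %/% cfg$nElements
  els <- withStream(seed, "elements", {
    len <- sample(cfg$elementLenRange[1]:cfg$elementLenRange[2],
                  cfg$nElements, replace = TRUE)
    lo <- cfg$exonZone + 10L
    start <- vapply(seq_len(cfg$nElements), function(i) {
      hi <- slotLen - len[i] - 10L
      (i - 1L) * slotLen + sample(lo:hi, 1L)
    }, 0L)
    nIS <- round(cfg$classFractions[["ingroup_specific"]] * cfg$nElements)
    nSh <- round(cfg$classFractions[["shared"]] * cfg$nElements)
    cls <- sample(c(rep("ingroup_specific", nIS), rep("shared", nSh),
                    rep("decoy", cfg$nElements - nIS - nSh)))
    data.frame(element = sprintf("el_%03d", seq_len(cfg$nElements)),
               start = start, end = start + len - 1L, class = cls,
               stringsAsFactors = FALSE)
  })

  ## species genomes -----------------------------------------------------
  allSpecies <- c(cfg$ingroup, cfg$outgroup)
  subProb <- c(cfg$ingroupSubProb, cfg$outgroupSubProb)
  isOutgroup <- c(rep(FALSE, length(cfg$ingroup)), rep(TRUE, length(cfg$outgroup)))
  decoyKeep <- cfg$ingroup[seq_len(min(cfg$decoyConservedSpecies,
                                       length(cfg$ingroup)))]
  spChars <- list()
  conservedIn <- lapply(seq_len(nrow(els)), function(i) character())
  for (k in seq_along(allSpecies)) {
    sp <- allSpecies[k]
    spChars[[sp]] <- withStream(seed, paste0("species:", sp), {
      ch <- .mutate(refChars, subProb[k])
      for (i in seq_len(nrow(els))) {
        replace <- (els$class[i] == "ingroup_specific" && isOutgroup[k]) ||
          (els$class[i] == "decoy" && !(sp %in% decoyKeep))
        if (replace)
          ch[els$start[i]:els$end[i]] <-
            sample(c("A", "C", "G", "T"), els$end[i] - els$start[i] + 1L,
                   replace = TRUE)
      }
      ch
    })
    for (i in seq_len(nrow(els))) {
      kept <- !((els$class[i] == "ingroup_specific" && isOutgroup[k]) ||
                (els$class[i] == "decoy" && !(sp %in% decoyKeep)))
      if (kept) conservedIn[[i]] <- c(conservedIn[[i]], sp)
    }
  }

  ## write sequence files ------------------------------------------------
  refSeq <- paste(refChars, collapse = "")
  writeGenome(setNames(Biostrings::BStringSet(refSeq), cfg$chrom), P("reference.fa"))
  paths <- list(reference = P("reference.fa"))
  for (sp in allSpecies) {
    f <- P(paste0("species_", sp, ".fa"))
    writeGenome(setNames(Biostrings::BStringSet(paste(spChars[[sp]], collapse = "")),
                         cfg$chrom), f)
    paths[[paste0("species_", sp)]] <- f
  }
  elSeqs <- Biostrings::BStringSet(substring(refSeq, els$start, els$end))
  names(elSeqs) <- els$element
  writeGenome(elSeqs, P("elements.fa"))
  paths$elements <- P("elements.fa")

  ## fragmented assembly -------------------------------------------------
  ref <- setNames(Biostrings::BStringSet(refSeq), cfg$chrom)
  asm <- if (cfg$nBreaks > 0)
    fragmentAssembly(ref, cfg$nBreaks, gapLen = cfg$gapLen,
                     seed = streamSeed(seed, "fragment"),
                     avoid = GenomicRanges::GRanges(cfg$chrom,
                       IRanges::IRanges(els$start, els$end)))
  else ref
  writeGenome(asm, P("assembly.fa"))
  paths$assembly <- P("assembly.fa")

  ## MAF: one block per element ------------------------------------------
  blocks <- lapply(seq_len(nrow(els)), function(i) {
    s <- els$start[i]; e <- els$end[i]; len <- e - s + 1L
    rows <- c(cfg$refSpecies, allSpecies)
    texts <- c(substring(refSeq, s, e),
               vapply(allSpecies, function(sp)
                 paste(spChars[[sp]][s:e], collapse = ""), ""))
    new("MafBlock", src = paste0(rows, ".", cfg$chrom),
        start = rep(s - 1L, length(rows)), size = rep(len, length(rows)),
        strand = rep("+", length(rows)),
        srcSize = rep(cfg$genomeLen, length(rows)), text = texts)
  })
  writeMaf(blocks, P("alignment.maf"))
  paths$maf <- P("alignment.maf")

  ## conserved-region call sets -----------------------------------------
  consAB <- withStream(seed, "conserved", {
    A <- list(); B <- list()
    for (i in seq_len(nrow(els))) {
      s <- els$start[i]; e <- els$end[i]; len <- e - s + 1L
      if (stats::runif(1) < 0.3) {
        # split call with a joinable gap (<= 10 bp)
        m <- s + len %/% 2L
        g <- sample(0:10, 1L)
        A[[length(A) + 1L]] <- c(s, m)
        B[[length(B) + 1L]] <- c(min(m + 1L + g, e), e)
      } else {
        A[[length(A) + 1L]] <- c(s, s + as.integer(ceiling(0.6 * len)) - 1L)
        B[[length(B) + 1L]] <- c(s + as.integer(floor(0.4 * len)), e)
      }
    }
    # short isolated noise calls (< 30 bp, dropped by the length filter)
    for (j in 1:5) {
      slot <- sample(cfg$nElements, 1L)
      pos <- (slot - 1L) * slotLen + sample(5:50, 1L)
      A[[length(A) + 1L]] <- c(pos, pos + sample(5:25, 1L))
    }
    list(A = do.call(rbind, A), B = do.call(rbind, B))
  })
  mkGr <- function(m) GenomicRanges::GRanges(cfg$chrom,
                                             IRanges::IRanges(m[, 1], m[, 2]))
  writeBed(GenomicRanges::sort(mkGr(consAB$A)), P("conserved_setA.bed"))
  writeBed(GenomicRanges::sort(mkGr(consAB$B)), P("conserved_setB.bed"))
  paths$conservedA <- P("conserved_setA.bed")
  paths$conservedB <- P("conserved_setB.bed")

  ## exons ----------------------------------------------------------------
  exons <- withStream(seed, "exons", {
    slots <- sample(cfg$nElements, min(cfg$nExons, cfg$nElements))
    len <- sample(cfg$exonLenRange[1]:cfg$exonLenRange[2], length(slots),
                  replace = TRUE)
    st <- (slots - 1L) * slotLen + 5L
    df <- data.frame(start = st, end = st + len - 1L)
    # a few exons clipping the leading edge of an element
    ovEl <- sample(which(els$class != "decoy"),
                   min(cfg$exonOverlapCount, sum(els$class != "decoy")))
    rbind(df, data.frame(start = els$start[ovEl] - 20L,
                         end = els$start[ovEl] + 39L))
  })
  exonGr <- GenomicRanges::sort(GenomicRanges::GRanges(
    cfg$chrom, IRanges::IRanges(exons$start, exons$end)))
  writeBed(exonGr, P("exons.bed"))
  paths$exons <- P("exons.bed")

  ## transposons ----------------------------------------------------------
  tpClasses <- c("SINE", "LINE", "LTR", "DNA")
  tp <- withStream(seed, "repeats", {
    # planted overlaps target non-decoy elements so every planted overlap
    # survives the species-support filter and lands on a real CNE
    eligible <- which(els$class != "decoy")
    nOv <- min(cfg$transposonOverlapCount, length(eligible))
    ovEl <- sample(eligible, nOv)
    rows <- data.frame(start = pmax(1L, els$end[ovEl] - 60L),
                       end = pmin(cfg$genomeLen, els$end[ovEl] + 100L),
                       class = tpClasses[(seq_len(nOv) - 1L) %% 4L + 1L],
                       element = els$element[ovEl], stringsAsFactors = FALSE)
    nBg <- cfg$nTransposons - nOv
    if (nBg > 0) {
      slots <- sample(seq_len(cfg$nElements), nBg)
      len <- sample(cfg$transposonLenRange[1]:cfg$transposonLenRange[2], nBg,
                    replace = TRUE)
      st <- (slots - 1L) * slotLen + 260L  # behind the exon zone head
      st <- pmin(st, (slots - 1L) * slotLen + cfg$exonZone - len)
      rows <- rbind(rows, data.frame(start = st, end = st + len - 1L,
                                     class = tpClasses[(seq_len(nBg) - 1L) %% 4L + 1L],
                                     element = "", stringsAsFactors = FALSE))
    }
    rows
  })
  tpGr <- GenomicRanges::GRanges(cfg$chrom, IRanges::IRanges(tp$start, tp$end))
  tpGr$repeat_class <- tp$class
  tpGr$family <- paste0(tp$class, "-fam")
  tpGr$repeat_name <- sprintf("tp_%03d", seq_along(tpGr))
  writeRepeatMaskerOut(tpGr, P("repeats.out"))
  paths$repeats <- P("repeats.out")

  ## outgroup element locations ------------------------------------------
  for (og in cfg$outgroup) {
    locs <- withStream(seed, paste0("outgroup:", og), {
      gapBp <- sample(200:5000, nrow(els), replace = TRUE)
      st <- cumsum(c(1L, (els$end - els$start + 1L)[-nrow(els)] +
                       gapBp[-nrow(els)]))
      data.frame(start = st, end = st + (els$end - els$start),
                 name = els$element, stringsAsFactors = FALSE)
    })
    gr <- GenomicRanges::GRanges("chrA", IRanges::IRanges(locs$start, locs$end))
    gr$name <- locs$name
    f <- P(paste0("outgroup_", og, ".bed"))
    writeBed(gr, f)
    paths[[paste0("outgroup_", og)]] <- f
  }

  ## truth tables ---------------------------------------------------------
  cneTruth <- subtractIntervals(
    GenomicRanges::GRanges(cfg$chrom, IRanges::IRanges(els$start, els$end)),
    exonGr)
  ovl <- GenomicRanges::findOverlaps(
    GenomicRanges::GRanges(cfg$chrom, IRanges::IRanges(els$start, els$end)),
    cneTruth, select = "first")
  truthEl <- data.frame(
    element = els$element, chrom = cfg$chrom,
    start = els$start, end = els$end,
    cne_start = GenomicRanges::start(cneTruth)[ovl],
    cne_end = GenomicRanges::end(cneTruth)[ovl],
    class = els$class,
    conserved_in = vapply(conservedIn, paste, "", collapse = ","),
    transposon = vapply(els$element, function(e) {
      i <- which(tp$element == e)
      if (length(i)) sprintf("tp_%03d", i[1L]) else ""
    }, ""),
    stringsAsFactors = FALSE)
  truthPairs <- data.frame(elementA = els$element[-nrow(els)],
                           elementB = els$element[-1L],
                           stringsAsFactors = FALSE)
  write.table(truthEl, P("truth_elements.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(truthPairs, P("truth_pairs.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  paths$truth_elements <- P("truth_elements.tsv")
  paths$truth_pairs <- P("truth_pairs.tsv")

  invisible(list(dir = dir, paths = paths,
                 truth = list(elements = truthEl, pairs = truthPairs),
                 config = cfg))
}

#' Fragment an assembly at random positions
#'
#' Cuts the input scaffolds at `nBreaks` uniformly chosen internal
#' positions (optionally avoiding given intervals, e.g. planted elements)
#' and returns either the separate fragments or, with
#' `asScaffold = TRUE`, each original scaffold re-joined from its
#' fragments with `gapLen` Ns so the cuts register as assembly gaps.
#' `nBreaks = 0` returns the input unchanged.
#'
#' @param assembly a named `BStringSet`.
#' @param nBreaks number of cut points.
#' @param gapLen N-run length used when re-joining (default 100).
#' @param seed RNG seed for break placement.
#' @param avoid optional `GRanges`; breaks are re-drawn (up to 100 times)
#'   until they fall outside these intervals.
#' @param asScaffold return re-joined scaffolds instead of fragments.
#' @return a `BStringSet`.
#' @export
fragmentAssembly <- function(assembly, nBreaks, gapLen = 100L, seed = 1L,
                             avoid = NULL, asScaffold = FALSE) {
  nBreaks <- .assertCount(nBreaks, "nBreaks")
  if (nBreaks == 0L) return(assembly)
  widths <- Biostrings::width(assembly)
  avoidDf <- if (!is.null(avoid) && length(avoid))
    data.frame(chrom = as.character(GenomicRanges::seqnames(avoid)),
               start = GenomicRanges::start(avoid),
               end = GenomicRanges::end(avoid))
  else NULL
  breaks <- withStream(seed, "breaks", {
    # a break after position p of scaffold i; interior positions only
    total <- sum(pmax(0, widths - 1))
    drawOne <- function() {
      for (try in 1:100) {
        g <- sample.int(total, 1L)
        i <- 1L
        while (g > widths[i] - 1L) { g <- g - (widths[i] - 1L); i <- i + 1L }
        nm <- names(assembly)[i]
        if (is.null(avoidDf) ||
            !any(avoidDf$chrom == nm & avoidDf$start <= g + 1L &
                 avoidDf$end >= g))
          return(c(i, g))
      }
      c(i, g)
    }
    t(vapply(seq_len(nBreaks), function(.) drawOne(), c(0, 0)))
  })
  out <- character(); nms <- character()
  for (i in seq_along(assembly)) {
    cuts <- sort(unique(breaks[breaks[, 1] == i, 2]))
    seq <- as.character(assembly[[i]])
    bounds <- c(0, cuts, widths[i])
    pieces <- substring(seq, bounds[-length(bounds)] + 1, bounds[-1])
    pieces <- pieces[nchar(pieces) > 0]
    if (asScaffold) {
      out <- c(out, paste(pieces, collapse = strrep("N", gapLen)))
      nms <- c(nms, names(assembly)[i])
    } else if (length(pieces) == 1L) {
      out <- c(out, pieces); nms <- c(nms, names(assembly)[i])
    } else {
      out <- c(out, pieces)
      nms <- c(nms, paste0(names(assembly)[i], "_p", seq_along(pieces)))
    }
  }
  setNames(Biostrings::BStringSet(out), nms)
}
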