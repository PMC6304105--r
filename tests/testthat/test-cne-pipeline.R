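test_that("conserved-set merging joins across small gaps and length-filters", {
  # setA [0,20), setB [25,60): gap 5 -> one region [0,60)
  setA <- GRanges("chr1", IRanges(1, 20))
  setB <- GRanges("chr1", IRanges(26, 60))
  r <- mergeConservedSets(setA, setB)
  expect_equal(rangesMatrix(r), cbind(start = 1, end = 60))
  expect_identical(r$source, "setA,setB")
  # an isolated 29 bp region is dropped
  r2 <- mergeConservedSets(GRanges("chr1", IRanges(100, 128)),
                           GRanges())
  expect_length(r2, 0)
  # single-source labels
  r3 <- mergeConservedSets(GRanges("chr1", IRanges(1, 40)),
                           GRanges("chr1", IRanges(500, 540)))
  expect_identical(r3$source, c("setA", "setB"))
})

test_that("conserved-set merging matches the bitmap oracle", {
  set.seed(61)
  for (rep in 1:40) {
    a <- randomIntervals(sample(3:25, 1), 8000, maxLen = 120)
    b <- randomIntervals(sample(3:25, 1), 8000, maxLen = 120)
    r <- mergeConservedSets(a, b, joinGap = 10, minLen = 30)
    m <- bitmapMerge(c(granges(a), granges(b)), 8000, 10)
    m <- m[m[, "end"] - m[, "start"] + 1 >= 30, , drop = FALSE]
    expect_equal(rangesMatrix(r), m)
  }
})

mkBlock <- function(refText, spTexts, refStart0 = 0, chrom = "chr1",
                    srcSize = 100000L) {
  n <- 1L + length(spTexts)
  new("MafBlock",
      src = c(paste0("tegu.", chrom), paste0(names(spTexts), ".", chrom)),
      start = rep(as.integer(refStart0), n),
      size = as.integer(nchar(gsub("-", "", c(refText, unname(spTexts))))),
      strand = rep("+", n), srcSize = rep(srcSize, n),
      text = c(refText, unname(spTexts)))
}

test_that("support windows mark well-aligned runs and honor the boundary", {
  # 50 perfectly matching columns -> one 50 bp window
  s <- randomSeqStr(50)
  w <- computeSupportWindows(list(mkBlock(s, c(sp1 = s), refStart0 = 100)),
                             "tegu")
  expect_equal(rangesMatrix(w), cbind(start = 101, end = 150))
  expect_identical(w$species, "sp1")

  # 30 columns with 17 matches (56.7%) -> no window; 18 matches (60%) -> window
  r <- strrep("A", 30)
  q17 <- paste0(strrep("A", 17), strrep("C", 13))
  q18 <- paste0(strrep("A", 18), strrep("C", 12))
  expect_length(computeSupportWindows(list(mkBlock(r, c(sp1 = q17))), "tegu"), 0)
  w <- computeSupportWindows(list(mkBlock(r, c(sp1 = q18))), "tegu")
  expect_equal(rangesMatrix(w), cbind(start = 1, end = 30))

  # reference row missing
  blk <- mkBlock(s, c(sp1 = s))
  expect_error(computeSupportWindows(list(blk), "otherref"), "block 1")
})

test_that("window marking matches brute-force enumeration on random blocks", {
  set.seed(62)
  for (rep in 1:30) {
    n <- sample(40:300, 1)
    r <- randomSeqChars(n)
    q <- r
    nm <- sample(0:floor(n * 0.6), 1)
    pos <- sample(n, nm)
    q[pos] <- sample(c("A", "C", "G", "T", "-"), nm, replace = TRUE)
    blk <- mkBlock(paste(r, collapse = ""),
                   c(spX = paste(q, collapse = "")), refStart0 = 17)
    w <- computeSupportWindows(list(blk), "tegu", win = 30, minId = 0.6)
    isMatch <- q == r & q != "-"
    marked <- markWindowsBrute(isMatch, 30, 0.6)
    mm <- bitmapToRanges(c(rep(FALSE, 17), marked))
    mm <- mm[mm[, "end"] - mm[, "start"] + 1 >= 30, , drop = FALSE]
    expect_equal(rangesMatrix(w), mm, info = paste("rep", rep))
  }
})

test_that("gapped reference columns are excluded from window columns", {
  # reference gap column is skipped; the remaining 30 ref-base columns match
  r <- paste0(substr(strrep("ACGT", 8), 1, 15), "-",
              substr(strrep("ACGT", 8), 16, 30))
  q <- chartr("-", "A", r)  # base under the ref gap
  w <- computeSupportWindows(list(mkBlock(r, c(sp1 = q))), "tegu")
  expect_equal(rangesMatrix(w), cbind(start = 1, end = 30))
})

test_that("species support keeps regions at the threshold and drops below", {
  region <- GRanges("chr1", IRanges(1000, 1200))
  region$region_id <- "r1"
  mkW <- function(nsp) {
    w <- GRanges("chr1", IRanges(rep(1050, nsp), rep(1120, nsp)))
    w$species <- paste0("sp", seq_len(nsp))
    w
  }
  expect_length(speciesSupportFilter(region, mkW(4), 4), 1)
  expect_length(speciesSupportFilter(region, mkW(3), 4), 0)
  kept <- speciesSupportFilter(region, mkW(5), 4)
  expect_equal(kept$n_species, 5L)
  expect_identical(kept$supporting_species, "sp1,sp2,sp3,sp4,sp5")
})

test_that("CNE derivation subtracts exons and length-filters fragments", {
  region <- GRanges("chr1", IRanges(101, 200))
  region$region_id <- "r1"
  # exon [150,160) -> CNEs [100,150) and [160,200) in 0-based terms
  cnes <- deriveCnes(region, GRanges("chr1", IRanges(151, 160)))
  expect_equal(rangesMatrix(cnes), cbind(start = c(101, 161), end = c(150, 200)))
  expect_identical(cnes$parent_region, c("r1", "r1"))
  # remaining 25 bp fragment is dropped
  cnes2 <- deriveCnes(region, GRanges("chr1", IRanges(101, 175)))
  expect_length(cnes2, 0)
})

test_that("lineage classification partitions by ingroup/outgroup support", {
  cne <- GRanges("chr1", IRanges(1000, 1100))
  mkW <- function(species) {
    w <- GRanges("chr1", IRanges(rep(1000, length(species)),
                                 rep(1100, length(species))))
    w$species <- species
    w
  }
  ing <- paste0("sq", 1:9); out <- c("human", "mouse", "chicken")
  cls <- function(w) classifyLineage(cne, w, ing, out)$lineage_class
  expect_identical(cls(mkW(ing[1:7])), "ingroup_specific")
  expect_identical(cls(mkW(c(ing[1:7], "human"))), "shared")
  expect_identical(cls(mkW(ing[1:5])), "unclassified")
  expect_error(classifyLineage(cne, mkW("alien"), ing, out), "not declared")
  expect_error(classifyLineage(cne, mkW(ing[1]), ing, c(ing[1], out)),
               "disjoint")
})

test_that("lineage classes are mutually exclusive and exhaustive", {
  set.seed(63)
  cnes <- GRanges("chr1", IRanges(seq(1, 20000, by = 400), width = 100))
  allSp <- c(paste0("sq", 1:9), c("human", "mouse", "chicken"))
  ws <- lapply(allSp, function(sp) {
    n <- sample(10:30, 1)
    s <- sample(20000, n)
    w <- GRanges("chr1", IRanges(s, width = sample(30:80, n, replace = TRUE)))
    w$species <- sp
    w
  })
  w <- do.call(c, ws)
  cls <- classifyLineage(cnes, w, paste0("sq", 1:9),
                         c("human", "mouse", "chicken"))
  expect_true(all(cls$lineage_class %in%
                    c("ingroup_specific", "shared", "unclassified")))
  tab <- table(cls$lineage_class)
  expect_equal(sum(tab), length(cnes))
})

test_that("RepeatMasker .out parsing converts coordinates and classes", {
  f <- withr::local_tempfile(fileext = ".out")
  writeLines(c("header1", "header2", "",
               " 1000 0.1 0.0 0.0 chr1 101 200 (0) + BovB LINE/RTE-BovB 1 100 (0) 1",
               " 900 0.2 0.0 0.0 chr1 500 540 (0) + AT_rich Simple_repeat 1 41 (0) 2",
               " 800 0.2 0.0 0.0 chr1 900 980 (0) + MIR3 SINE?/MIR 1 81 (0) 3"), f)
  rp <- readRepeatMaskerOut(f)
  # 1-based inclusive stays 101..200 internally (1-based closed)
  expect_equal(start(rp)[1], 101)
  expect_equal(end(rp)[1], 200)
  expect_identical(rp$repeat_class, c("LINE", "other", "SINE"))
  expect_identical(rp$family[1], "RTE-BovB")
  writeLines(c("h", "h", "", " 1000 0.1 0.0 0.0 chr1 10x 200 (0) + a LINE 1 1 (0) 1"), f)
  expect_error(readRepeatMaskerOut(f), "line 4.*coordinate")
})

test_that("repeat annotations round-trip through the .out writer", {
  gr <- GRanges("chr1", IRanges(c(101, 900), c(200, 1100)))
  gr$repeat_class <- c("LINE", "DNA")
  gr$family <- c("RTE-BovB", "hAT")
  gr$repeat_name <- c("BovB", "Charlie")
  f <- withr::local_tempfile(fileext = ".out")
  writeRepeatMaskerOut(gr, f)
  back <- readRepeatMaskerOut(f)
  expect_equal(start(back), start(gr))
  expect_equal(end(back), end(gr))
  expect_identical(back$repeat_class, gr$repeat_class)
  expect_identical(back$family, gr$family)
})

test_that("transposon overlap applies the per-feature 30 bp rule", {
  cne <- GRanges("chr1", IRanges(1, 100))   # [0,100) in 0-based terms
  mkRep <- function(s, e, cl = "LINE") {
    r <- GRanges("chr1", IRanges(s, e)); r$repeat_class <- cl; r
  }
  # overlap 20 < 30: not counted
  expect_equal(nOverlapping(transposonOverlap(cne, mkRep(81, 140))), 0)
  # overlap exactly 30: counted
  rep30 <- transposonOverlap(cne, mkRep(71, 140))
  expect_equal(nOverlapping(rep30), 1)
  expect_equal(overlappedBases(rep30), 30)
  expect_equal(unname(classBases(rep30)["LINE"]), 30)
  # non-transposon classes are ignored entirely
  expect_equal(nOverlapping(transposonOverlap(cne, mkRep(1, 100, "other"))), 0)
  # two 20 bp overlaps: only the summed mode counts the CNE
  reps <- c(mkRep(1, 20), mkRep(81, 100))
  expect_equal(nOverlapping(transposonOverlap(cne, reps)), 0)
  expect_equal(nOverlapping(transposonOverlap(cne, reps, sumOverlaps = TRUE)), 1)
})

test_that("raising the overlap threshold never adds overlapping CNEs", {
  set.seed(64)
  cnes <- GRanges("chr1", IRanges(seq(1, 30000, by = 600), width = 120))
  reps <- randomIntervals(60, 30000, maxLen = 150)
  reps$repeat_class <- sample(c("SINE", "LINE", "LTR", "DNA", "other"),
                              60, replace = TRUE)
  prev <- Inf
  for (mo in c(1, 10, 30, 60, 120)) {
    n <- nOverlapping(transposonOverlap(cnes, reps, mo))
    expect_lte(n, prev)
    prev <- n
  }
})

test_that("every CNE base is conserved and non-exonic (pipeline conservation)", {
  sim <- simulateClade(smallCladeConfig(seed = 71), withr::local_tempdir())
  setA <- readBed(sim$paths$conservedA)
  setB <- readBed(sim$paths$conservedB)
  exons <- readBed(sim$paths$exons)
  regions <- mergeConservedSets(setA, setB)
  cnes <- deriveCnes(regions, exons)
  L <- sim$config$genomeLen
  cneBm <- bitmapOf(cnes, L)
  regBm <- bitmapOf(regions, L)
  exBm <- bitmapOf(exons, L)
  expect_true(all(regBm[cneBm]))     # CNE bases are conserved bases
  expect_false(any(exBm[cneBm]))     # and never exonic
})
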