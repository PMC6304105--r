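mkHit <- function(qid = "q1", qlen = 100, qs = 1, qe = 100, tname = "s1",
                  ts = 1001, te = 1100, strand = "+", matches = 100,
                  mismatches = 0, qgaps = 0, tgaps = 0) {
  gr <- GRanges(tname, IRanges(ts, te), strand = strand)
  gr$query_id <- qid; gr$query_len <- qlen; gr$qstart <- qs; gr$qend <- qe
  gr$matches <- matches; gr$mismatches <- mismatches
  gr$query_gaps <- qgaps; gr$target_gaps <- tgaps
  gr
}

test_that("PAF lines parse into consistent hits", {
  f <- withr::local_tempfile(fileext = ".paf")
  writeLines("q1\t100\t0\t100\t+\ts1\t5000\t1000\t1100\t100\t100\t60\tcg:Z:100=", f)
  h <- readPaf(f)
  expect_equal(h$matches, 100)
  expect_equal(hitIdentity(h), 1.0)
  expect_equal(hitCoverage(h), 1.0)
  expect_equal(start(h), 1001)  # 0-based converted

  # cigar-implied span inconsistent with the stated span
  writeLines("q1\t100\t0\t100\t+\ts1\t5000\t1000\t1090\t90\t100\t60\tcg:Z:100=", f)
  expect_error(readPaf(f), "line 1.*target span")
  # missing cigar
  writeLines("q1\t100\t0\t100\t+\ts1\t5000\t1000\t1100\t100\t100\t60", f)
  expect_error(readPaf(f), "line 1.*cigar")
})

test_that("hits round-trip through PAF with identical fields", {
  set.seed(31)
  f <- withr::local_tempfile(fileext = ".paf")
  for (rep in 1:20) {
    m <- sample(50:200, 1); x <- sample(0:30, 1)
    i <- sample(0:10, 1); d <- sample(0:10, 1)
    qlen <- m + x + i + 40
    qs <- sample(1:20, 1); qe <- qs + m + x + i - 1
    ts <- sample(1000:5000, 1); te <- ts + m + x + d - 1
    h <- mkHit(qid = paste0("q", rep), qlen = qlen, qs = qs, qe = qe,
               ts = ts, te = te, strand = sample(c("+", "-"), 1),
               matches = m, mismatches = x, qgaps = d, tgaps = i)
    writePaf(h, f)
    back <- readPaf(f)
    for (col in c("query_id", "query_len", "qstart", "qend",
                  "matches", "mismatches", "query_gaps", "target_gaps"))
      expect_equal(mcols(back)[[col]], mcols(h)[[col]], info = col)
    expect_equal(start(back), start(h))
    expect_equal(end(back), end(h))
    expect_equal(as.character(strand(back)), as.character(strand(h)))
  }
})

test_that("identity and coverage honor thresholds and modes", {
  h <- mkHit(matches = 60, mismatches = 40, qe = 100)
  expect_equal(hitIdentity(h), 0.60)   # exact boundary value
  h2 <- mkHit(matches = 60, mismatches = 20, qgaps = 10, tgaps = 10,
              qe = 90, te = 1090)
  expect_equal(hitIdentity(h2, "gap-inclusive"), 0.60)
  expect_equal(hitIdentity(h2, "gap-exclusive"), 0.75)
  h3 <- mkHit(qs = 11, qe = 90, matches = 80, te = 1080)
  expect_equal(hitCoverage(h3), 0.80)
})

test_that("MAF blocks parse, validate and round-trip", {
  f <- withr::local_tempfile(fileext = ".maf")
  writeLines(c("##maf version=1", "", "a score=1",
               "s tegu.chr1 10 40 + 1000 ACGTACGTACGTACGTACGTACGTACGTACGTACGTACGT",
               "s sp1.chrA   5 40 + 900  ACGTACGTACGTACGTACGTACGTACGTACGTACGTACGT"),
             f)
  blocks <- readMaf(f)
  expect_length(blocks, 1)
  expect_identical(mafSpecies(blocks[[1]]), c("tegu", "sp1"))
  expect_equal(mafRow(blocks[[1]], "sp1"), 2L)

  # gapped rows: ungapped size must match
  writeLines(c("a", "s tegu.chr1 0 4 + 100 AC-GT", "s sp1.chrA 0 5 + 100 ACCGT"), f)
  b <- readMaf(f)[[1]]
  expect_equal(b@size, c(4L, 5L))

  writeLines(c("a", "s tegu.chr1 0 4 + 100 ACGT", "s sp1.chrA 0 5 + 100 ACGTT"), f)
  expect_error(readMaf(f), "block 1")
})

test_that("MAF round-trips through the writer", {
  b <- new("MafBlock", src = c("tegu.chr1", "sp1.chrA"),
           start = c(10L, 5L), size = c(6L, 5L), strand = c("+", "-"),
           srcSize = c(1000L, 900L), text = c("ACGTAC", "AC-TAC"))
  f <- withr::local_tempfile(fileext = ".maf")
  writeMaf(list(b, b), f)
  back <- readMaf(f)
  expect_length(back, 2)
  expect_equal(back[[1]]@src, b@src)
  expect_equal(back[[1]]@start, b@start)
  expect_equal(back[[1]]@strand, b@strand)
  expect_equal(back[[1]]@text, b@text)
})

test_that("entropy quality filter combines identity and composition", {
  # zero entropy: 30 identical A columns
  expect_false(passesEntropyQuality(strrep("A", 30), strrep("A", 30)))
  # maximal entropy: equal ACGT composition
  s <- strrep("ACGT", 8)
  expect_true(passesEntropyQuality(s, s))
  # composition (.4,.3,.2,.1): H = 1.846 bits >= 1.8
  q <- paste0(strrep("A", 12), strrep("C", 9), strrep("G", 6), strrep("T", 3))
  expect_true(passesEntropyQuality(q, q))
  H <- -sum(c(.4, .3, .2, .1) * log2(c(.4, .3, .2, .1)))
  expect_gt(H, 1.8)
  # same composition but below the identity threshold fails
  qBad <- chartr("ACGT", "CAGT", q)  # mismatches in 21/30 columns
  expect_false(passesEntropyQuality(q, qBad, minId = 0.8))
})

test_that("entropy filter equals brute-force window enumeration", {
  set.seed(77)
  for (rep in 1:25) {
    n <- sample(30:80, 1)
    r <- randomSeqChars(n)
    q <- r
    nm <- sample(0:floor(n / 2), 1)
    pos <- sample(n, nm)
    q[pos] <- sample(c("A", "C", "G", "T", "-"), nm, replace = TRUE)
    rs <- paste(r, collapse = ""); qs <- paste(q, collapse = "")
    expect_equal(passesEntropyQuality(rs, qs),
                 entropyQualityBrute(rs, qs), info = paste("rep", rep))
  }
})

test_that("pairwise difference summary classifies every column once", {
  # all-match
  s <- randomSeqStr(200)
  st <- summarizeDifferences(s, s)
  expect_equal(unname(percentBreakdown(st)), c(100, 0, 0, 0))
  # 1000 columns: 998 match, 1 mismatch, 1 insertion
  ref <- paste0(strrep("A", 500), "-", strrep("C", 499))
  qry <- paste0(strrep("A", 499), "G", "T", strrep("C", 499))
  st <- summarizeDifferences(ref, qry)
  cc <- columnCounts(st)
  expect_equal(cc[["columns"]], 1000)
  expect_equal(cc[["match"]], 998)
  expect_equal(cc[["mismatch"]], 1)
  expect_equal(cc[["ins"]], 1)
  expect_equal(cc[["refBases"]], 999)
  # percentages over reference bases
  expect_equal(percentBreakdown(st)[["substitution"]], 100 / 999)
  expect_equal(percentBreakdown(st)[["insertion"]], 100 / 999)
  expect_error(summarizeDifferences("A-G", "A-G"), "gaps on both")
})

test_that("difference summary matches an independent recount", {
  set.seed(55)
  for (rep in 1:20) {
    n <- sample(100:400, 1)
    r <- randomSeqChars(n); q <- randomSeqChars(n)
    # sprinkle one-sided gaps
    gp <- sample(n, sample(0:20, 1))
    half <- seq_along(gp) %% 2 == 0
    r[gp[half]] <- "-"; q[gp[!half]] <- "-"
    st <- summarizeDifferences(paste(r, collapse = ""), paste(q, collapse = ""))
    cc <- columnCounts(st)
    expect_equal(cc[["match"]], sum(r != "-" & q != "-" & r == q))
    expect_equal(cc[["mismatch"]], sum(r != "-" & q != "-" & r != q))
    expect_equal(cc[["ins"]], sum(r == "-" & q != "-"))
    expect_equal(cc[["del"]], sum(r != "-" & q == "-"))
    expect_equal(sum(cc[c("match", "mismatch", "ins", "del")]), n)
  }
})
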