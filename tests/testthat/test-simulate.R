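test_that("identical seeds produce byte-identical output files", {
  cfg <- smallCladeConfig(seed = 42)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  s1 <- simulateClade(cfg, d1)
  s2 <- simulateClade(cfg, d2)
  f1 <- sort(list.files(d1)); f2 <- sort(list.files(d2))
  expect_identical(f1, f2)
  h1 <- tools::md5sum(file.path(d1, f1))
  h2 <- tools::md5sum(file.path(d2, f2))
  expect_identical(unname(h1), unname(h2))
  # a different seed changes the genome
  s3 <- simulateClade(smallCladeConfig(seed = 43), withr::local_tempdir())
  expect_false(identical(
    unname(tools::md5sum(s3$paths$reference)),
    unname(tools::md5sum(s1$paths$reference))))
})

test_that("every emitted file parses cleanly by its reader", {
  sim <- simulateClade(smallCladeConfig(seed = 44), withr::local_tempdir())
  expect_s4_class(readGenome(sim$paths$reference), "BStringSet")
  expect_s4_class(readGenome(sim$paths$assembly), "BStringSet")
  expect_s4_class(readGenome(sim$paths$elements), "BStringSet")
  expect_s4_class(readGenome(sim$paths$species_squamate1), "BStringSet")
  expect_s4_class(readBed(sim$paths$conservedA), "GRanges")
  expect_s4_class(readBed(sim$paths$conservedB), "GRanges")
  expect_s4_class(readBed(sim$paths$exons), "GRanges")
  expect_s4_class(readBed(sim$paths$outgroup_human), "GRanges")
  expect_s4_class(readMaf(sim$paths$maf)[[1]], "MafBlock")
  expect_s4_class(readRepeatMaskerOut(sim$paths$repeats), "GRanges")
  truth <- read.delim(sim$paths$truth_elements)
  expect_identical(sort(unique(truth$class)),
                   c("decoy", "ingroup_specific", "shared"))
})

test_that("truth intervals match the reference and element sequences", {
  sim <- simulateClade(smallCladeConfig(seed = 45), withr::local_tempdir())
  ref <- as.character(readGenome(sim$paths$reference)[[1]])
  els <- readGenome(sim$paths$elements)
  truth <- sim$truth$elements
  for (i in seq_len(nrow(truth))) {
    expect_identical(substr(ref, truth$start[i], truth$end[i]),
                     as.character(els[[truth$element[i]]]))
  }
})

test_that("the noise-free limit conserves every non-replaced locus exactly", {
  cfg <- smallCladeConfig(seed = 46, ingroupSubProb = 0, outgroupSubProb = 0)
  sim <- simulateClade(cfg, withr::local_tempdir())
  maf <- readMaf(sim$paths$maf)
  w <- computeSupportWindows(maf, "tegu")
  regions <- mergeConservedSets(readBed(sim$paths$conservedA),
                                readBed(sim$paths$conservedB))
  kept <- speciesSupportFilter(regions, w, 4)
  cnes <- deriveCnes(kept, readBed(sim$paths$exons))
  cls <- classifyLineage(cnes, w, cfg$ingroup, cfg$outgroup)
  truth <- sim$truth$elements
  # every planted non-decoy element must carry its planted label; no decoy
  # region survives the species-support filter
  for (i in which(truth$class != "decoy")) {
    hit <- findOverlaps(GRanges(truth$chrom[i],
                                IRanges(truth$start[i], truth$end[i])),
                        cls, select = "first")
    expect_false(is.na(hit))
    expect_identical(cls$lineage_class[hit], truth$class[i])
  }
  decoys <- truth[truth$class == "decoy", ]
  expect_equal(sum(countOverlaps(
    GRanges(decoys$chrom, IRanges(decoys$start, decoys$end)), cnes)), 0)
})

test_that("simulated genomes have near-uniform base composition", {
  sim <- simulateClade(simulationConfig(seed = 47, genomeLen = 100000L,
                                        nElements = 25L),
                       withr::local_tempdir())
  ref <- readGenome(sim$paths$reference)
  freq <- Biostrings::letterFrequency(ref, c("A", "C", "G", "T"))
  expect_true(all(abs(freq / 100000 - 0.25) < 0.01))
})

test_that("fragmentation conserves sequence and respects nBreaks", {
  set.seed(81)
  asm <- Biostrings::BStringSet(c(chr = randomSeqStr(10000)))
  expect_identical(fragmentAssembly(asm, 0), asm)
  frag <- fragmentAssembly(asm, 3, seed = 5)
  expect_equal(length(frag), 4)
  expect_equal(sum(width(frag)), 10000)
  expect_identical(paste(as.character(frag), collapse = ""),
                   as.character(asm[[1]]))
  # re-joined form registers the cuts as assembly gaps
  joined <- fragmentAssembly(asm, 3, gapLen = 40, seed = 5, asScaffold = TRUE)
  expect_equal(sort(splitIntoContigs(joined, 25)), sort(width(frag)))
})

test_that("break positions avoid protected intervals when asked", {
  set.seed(82)
  asm <- Biostrings::BStringSet(c(chr = randomSeqStr(5000)))
  avoid <- GRanges("chr", IRanges(seq(1, 4500, by = 500), width = 400))
  for (s in 1:5) {
    frag <- fragmentAssembly(asm, 4, seed = s, avoid = avoid)
    cuts <- cumsum(width(frag))
    cuts <- cuts[-length(cuts)]
    inAvoid <- vapply(cuts, function(p)
      any(start(avoid) <= p + 1 & end(avoid) >= p), TRUE)
    expect_false(any(inAvoid))
  }
})

test_that("truth intervals project to full-identity hits without noise", {
  cfg <- smallCladeConfig(seed = 48, nBreaks = 4L)
  sim <- simulateClade(cfg, withr::local_tempdir())
  asm <- readGenome(sim$paths$assembly)
  expect_gt(length(asm), 1)
  els <- readGenome(sim$paths$elements)
  best <- filterHits(mapElements(els, asm))
  # breaks avoid planted elements: every element recovered at identity 1.0
  expect_equal(sort(unique(best$query_id)), sort(names(els)))
  expect_true(all(best$identity == 1.0))
})
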