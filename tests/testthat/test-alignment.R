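test_that("readAlignments yields primary mapped records, 0-based", {
  ctg <- c(tA = strrep("ACGT", 40))
  sam <- tempfile(fileext = ".sam")
  writeToySam(sam, ctg, list(
    list(qname = "r1", flag = 0L, rname = "tA", pos = 101L, mapq = 30L,
         seq = substr(ctg[[1]], 101, 130)),
    list(qname = "r2", flag = 4L, rname = "*", pos = 0L, mapq = 0L,
         seq = "ACGTACGTAC"),                       # unmapped
    list(qname = "r3", flag = 256L, rname = "tA", pos = 11L, mapq = 0L,
         seq = substr(ctg[[1]], 11, 40)),           # secondary
    list(qname = "r4", flag = 0L, rname = "tA", pos = 1L, mapq = 7L,
         seq = substr(ctg[[1]], 1, 25))))
  aln <- readAlignments(sam)
  expect_identical(nrow(aln), 2L)
  r1 <- aln[aln$read_id == "r1", ]
  expect_identical(r1$start, 100L)                  # POS 101 -> 0-based 100
  expect_identical(r1$end, 130L)
  expect_identical(r1$mapq, 30L)
})

test_that("readAlignments drops or rejects unknown contigs per policy", {
  ref <- buildReference(toyGenes("ACGTACGTAC", ids = "tA"))
  ctgs <- c(tA = as.character(contigs(ref)[[1]]), tZ = strrep("GATC", 10))
  sam <- tempfile(fileext = ".sam")
  writeToySam(sam, ctgs, list(
    list(qname = "a", flag = 0L, rname = "tA", pos = 1L, mapq = 30L,
         seq = substr(ctgs[["tA"]], 1, 10)),
    list(qname = "b", flag = 0L, rname = "tZ", pos = 1L, mapq = 30L,
         seq = substr(ctgs[["tZ"]], 1, 10))))
  expect_warning(aln <- readAlignments(sam, ref), "absent")
  expect_identical(aln$read_id, "a")
  expect_error(suppressWarnings(
    readAlignments(sam, ref, onUnknownContig = "error")), "absent")
})

test_that("naiveAlign places unique exact matches and flags ambiguity", {
  set.seed(5)
  ref <- randomRef(3, bodyLen = 80)
  cs <- as.character(contigs(ref))
  rd <- Biostrings::DNAStringSet(c(u1 = substr(cs[[1]], 11, 61)))
  aln <- naiveAlign(rd, ref)
  expect_identical(aln$start, 10L)
  expect_identical(aln$mapq, 30L)
  expect_identical(aln$end, 61L)
  # a read occurring in two contigs is ambiguous
  shared <- "ACGTACGTACGTACGTACGT"
  ref2 <- buildReference(toyGenes(c(paste0(shared, randomSeq(30)),
                                    paste0(randomSeq(30), shared)),
                                  ids = c("c1", "c2")))
  amb <- naiveAlign(Biostrings::DNAStringSet(c(x = shared)), ref2)
  expect_identical(amb$mapq, 0L)
  # no-hit reads are omitted
  none <- naiveAlign(Biostrings::DNAStringSet(c(z = strrep("A", 30))), ref)
  expect_identical(nrow(none), 0L)
})

test_that("naiveAlign recovers every true start of an error-free library", {
  sim <- simulateTRNAGenes(5, seed = 19)
  ref <- buildReference(sim$genes)
  truth <- plantModifications(ref, nContigs = 2, seed = 1)
  lib <- simulateLibrary(ref, truth, "treated",
                         simulationConfig(nReads = 4000), seed = 3)
  aln <- naiveAlign(lib$reads, ref)
  expect_identical(nrow(aln), length(lib$reads))
  uniq <- aln[aln$mapq == 30L, ]
  key <- match(uniq$read_id, lib$truth$read_id)
  expect_identical(uniq$start + 1L, lib$truth$start[key])
})

test_that("subtractPretrna removes exactly the flank-overlapping read names", {
  sim <- simulateTRNAGenes(6, seed = 29)
  ref <- buildReference(sim$genes, sim$genome)
  cfg <- simulationConfig(nReads = 4000, pretrnaFraction = 0.15)
  lib <- simulateLibrary(ref, NULL, "untreated", cfg, seed = 7)
  alnC <- naiveAlign(lib$reads, ref)
  alnG <- naiveAlign(lib$reads, refGenome(ref))
  sub <- subtractPretrna(alnC, alnG, flankRegions(ref))
  truthPre <- sort(lib$truth$read_id[lib$truth$frag_type == "pre_trna"])
  expect_identical(sub$removed, truthPre)            # set equality
  expect_false(any(sub$alignments$read_id %in% truthPre))
  # empty flank list is the identity
  idn <- subtractPretrna(alnC, alnG, GenomicRanges::GRanges())
  expect_identical(idn$alignments, alnC)
  expect_identical(idn$removed, character(0))
})

test_that("filterAlignments applies MAPQ, exclusion and dedup rules", {
  aln <- makeAln(c("a", "a", "p", "a"), c(5, 5, 9, 5), mapq = c(0, 30, 30, 30),
                 len = 20, read_id = c("r1", "r2", "r3", "r4"))
  expect_identical(filterAlignments(aln)$read_id, c("r2", "r3", "r4"))
  expect_identical(filterAlignments(aln, exclude = "p", mapqMin = 0)$contig,
                   c("a", "a", "a"))
  dd <- filterAlignments(aln, mapqMin = 0, dedup = TRUE)
  expect_identical(nrow(dd), 2L)                     # (a,5,25) and (p,9,29)
  # monotone: raising mapqMin never increases the row count
  for (q in c(0, 1, 10, 31))
    expect_lte(nrow(filterAlignments(aln, mapqMin = q)),
               nrow(filterAlignments(aln, mapqMin = max(q - 1, 0))))
})

test_that("countStartSites thresholds cells but keeps totals complete", {
  aln <- rbind(alnFromCounts("tA", c(rep(0L, 44), 12L, rep(0L, 5), 9L)),
               alnFromCounts("tB", c(3L, 3L)))
  sct <- countStartSites(aln, "treated", minSupport = 10)
  cts <- startCounts(sct)
  expect_identical(cts$count[cts$contig == "tA" & cts$pos == 45], 12L)
  expect_identical(cts$count[cts$contig == "tA" & cts$pos == 51], 0L)
  expect_identical(unname(libTotals(sct)[c("tA", "tB")]), c(21L, 6L))
  # conservation pre-zeroing
  raw <- startCounts(sct, zeroUnsupported = FALSE)
  expect_identical(vapply(split(raw$count, raw$contig), sum, numeric(1)),
                   vapply(libTotals(sct)[sort(names(libTotals(sct)))],
                          as.numeric, numeric(1)))
  # monotone in minSupport
  for (ms in c(1, 5, 10, 13)) {
    lo <- startCounts(countStartSites(aln, "treated", ms))
    hi <- startCounts(countStartSites(aln, "treated", ms + 1))
    expect_true(all(hi$count <= lo$count))
  }
})

test_that("coverageProfile depth matches summed interval lengths", {
  ref <- buildReference(toyGenes(randomSeq(70), ids = "tA"))
  aln <- makeAln("tA", 10, len = 51)
  cov <- coverageProfile(aln, ref)[["tA"]]
  expect_identical(cov[11:61], rep(1L, 51))
  expect_identical(sum(cov), 51L)
  expect_true(all(cov[c(1:10, 62:73)] == 0L))
  empty <- coverageProfile(makeAln(character(0), integer(0)), ref)
  expect_true(all(empty[["tA"]] == 0L))
  # oracle: total depth == sum of alignment lengths
  set.seed(2)
  aln2 <- makeAln("tA", sample(0:20, 30, TRUE), len = sample(10:40, 30, TRUE))
  aln2$end <- pmin(aln2$end, 73L)
  cov2 <- coverageProfile(aln2, ref)[["tA"]]
  expect_identical(sum(cov2), sum(aln2$end - aln2$start))
})
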