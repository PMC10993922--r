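test_that("simulateTRNAGenes is deterministic and embeds genes in the genome", {
  a <- simulateTRNAGenes(10, nDistinct = 8, seed = 5)
  b <- simulateTRNAGenes(10, nDistinct = 8, seed = 5)
  expect_identical(a, b)
  expect_identical(length(unique(a$genes$sequence)), 8L)
  gseq <- as.character(a$genome[[1]])
  for (i in seq_len(nrow(a$genes))) {
    g <- a$genes[i, ]
    expect_identical(substr(gseq, g$start + 1, g$end), g$sequence)
  }
  # fixed modification-context bases: D20(T), m3C32(C), m7G46(G), no G at 47-49
  bases <- function(s, p) substring(s, p, p)
  expect_true(all(bases(a$genes$sequence, 20) == "T"))
  expect_true(all(bases(a$genes$sequence, 32) == "C"))
  expect_true(all(bases(a$genes$sequence, 46) == "G"))
  for (p in 47:49) expect_true(all(bases(a$genes$sequence, p) != "G"))
})

test_that("plantModifications enforces base compatibility", {
  ref <- buildReference(toyGenes(c("AAGTT", "AACTT"), ids = c("g1", "g2")))
  # G at position 3 of g1 only
  t1 <- plantModifications(ref, position = 3, modType = "m7G")
  expect_identical(t1$contig, "g1")
  expect_error(
    plantModifications(ref, sites = data.frame(contig = "g2", position = 3,
                                               mod_type = "m7G",
                                               efficiency = 0.5)),
    "cannot plant m7G at g2:3")
  t2 <- plantModifications(ref, position = 3, modType = "m3C")
  expect_identical(t2$contig, "g2")
  # deterministic subset draw
  sim <- simulateTRNAGenes(12, seed = 2)
  ref2 <- buildReference(sim$genes)
  s1 <- plantModifications(ref2, nContigs = 5, seed = 9)
  s2 <- plantModifications(ref2, nContigs = 5, seed = 9)
  expect_identical(s1, s2)
  expect_identical(nrow(s1), 5L)
})

test_that("simulateLibrary conserves reads and is byte-deterministic", {
  sim <- simulateTRNAGenes(6, seed = 3)
  ref <- buildReference(sim$genes, sim$genome)
  truth <- plantModifications(ref, nContigs = 3, seed = 4)
  cfg <- simulationConfig(nReads = 3000, pretrnaFraction = 0.1)
  lib1 <- simulateLibrary(ref, truth, "treated", cfg, seed = 21)
  lib2 <- simulateLibrary(ref, truth, "treated", cfg, seed = 21)
  expect_identical(as.character(lib1$reads), as.character(lib2$reads))
  expect_identical(lib1$truth, lib2$truth)
  # conservation: one truth row per read, totalling nReads
  expect_identical(length(lib1$reads), 3000L)
  expect_identical(nrow(lib1$truth), 3000L)
  expect_identical(sum(table(lib1$truth$frag_type)), 3000L)
  f1 <- tempfile(fileext = ".fastq"); f2 <- tempfile(fileext = ".fastq")
  writeLibrary(lib1, f1); writeLibrary(lib2, f2)
  expect_identical(readLines(f1), readLines(f2))
  # untreated: no modification-directed cleavage
  libU <- simulateLibrary(ref, truth, "untreated", cfg, seed = 21)
  expect_false(any(libU$truth$frag_type %in%
                     c("cleaved_3prime", "cleaved_5prime")))
})

test_that("full-efficiency cleavage confines treated starts to N..N+3", {
  sim <- simulateTRNAGenes(3, seed = 8)
  ref <- buildReference(sim$genes)
  truth <- plantModifications(ref, contigs = names(contigs(ref))[1],
                              position = 46, efficiency = 1)
  cfg <- simulationConfig(nReads = 2000, pFivePrime = 0,
                          backgroundBreakRate = 0)
  lib <- simulateLibrary(ref, truth, "treated", cfg, seed = 1)
  onMod <- lib$truth[lib$truth$contig == truth$contig, ]
  expect_gt(nrow(onMod), 0)
  expect_true(all(onMod$frag_type == "cleaved_3prime"))
  expect_true(all(onMod$start >= 46 & onMod$start <= 49))
})

test_that("stop-offset frequencies follow the configured distribution", {
  sim <- simulateTRNAGenes(1, seed = 13)
  ref <- buildReference(sim$genes)
  truth <- plantModifications(ref, position = 46, efficiency = 1)
  cfg <- simulationConfig(nReads = 40000, readLength = 51,
                          stopOffsetProbs = c(0.25, 0.25, 0.25, 0.25),
                          pThreePrime = 1, pFivePrime = 0,
                          backgroundBreakRate = 0)
  lib <- simulateLibrary(ref, truth, "treated", cfg, seed = 17)
  off <- lib$truth$start - 46L
  expect_true(all(off %in% 0:3))
  freq <- as.numeric(table(factor(off, levels = 0:3))) / length(off)
  expect_true(all(abs(freq - 0.25) < 0.01))
})

test_that("3'/5' recovery asymmetry matches the configured odds", {
  sim <- simulateTRNAGenes(4, seed = 23)
  ref <- buildReference(sim$genes)
  truth <- plantModifications(ref, efficiency = 1)
  cfg <- simulationConfig(nReads = 20000, pThreePrime = 0.9,
                          pFivePrime = 0.15, backgroundBreakRate = 0,
                          minFragmentLength = 10)
  lib <- simulateLibrary(ref, truth, "treated", cfg, seed = 5)
  n3 <- sum(lib$truth$frag_type == "cleaved_3prime")
  n5 <- sum(lib$truth$frag_type == "cleaved_5prime")
  expect_gt(n3, 0); expect_gt(n5, 0)
  expect_lt(abs(n3 / n5 - 0.9 / 0.15), 0.6)
})

test_that("pre-tRNA reads hit flanks at the configured read fraction", {
  sim <- simulateTRNAGenes(8, seed = 31)
  ref <- buildReference(sim$genes, sim$genome)
  cfg <- simulationConfig(nReads = 10000, pretrnaFraction = 0.1)
  lib <- simulateLibrary(ref, NULL, "untreated", cfg, seed = 2)
  nPre <- sum(lib$truth$frag_type == "pre_trna")
  expect_lt(abs(nPre - 1000), 100)    # binomial: sd = 30
  pre <- lib$truth[lib$truth$frag_type == "pre_trna", ]
  gr <- GenomicRanges::GRanges(pre$chrom,
                               IRanges::IRanges(pre$gstart,
                                                pre$gstart + 51L - 1L))
  hits <- GenomicRanges::countOverlaps(gr, flankRegions(ref),
                                       minoverlap = 1L)
  expect_true(all(hits >= 1))
  libNo <- simulateLibrary(ref, NULL, "untreated",
                           simulationConfig(nReads = 2000), seed = 2)
  expect_false(any(libNo$truth$frag_type == "pre_trna"))
})

test_that("m3C and D sites cleave just like m7G in the simulator", {
  sim <- simulateTRNAGenes(2, seed = 41)
  ref <- buildReference(sim$genes)
  ctg <- names(contigs(ref))[1]
  truth <- data.frame(contig = ctg, position = c(32L, 20L),
                      mod_type = c("m3C", "D"), efficiency = 0.9)
  cfg <- simulationConfig(nReads = 4000, backgroundBreakRate = 0)
  lib <- simulateLibrary(ref, truth, "treated", cfg, seed = 6)
  clv <- lib$truth[lib$truth$frag_type == "cleaved_3prime", ]
  expect_gt(nrow(clv), 0)
  expect_true(all(clv$cleave_site %in% c(20L, 32L)))
})
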