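makeProfile <- function(rows, iso = "LysCTT", labels = character(0)) {
  new("AlignmentProfile", isoacceptor = iso, rows = rows, labels = labels)
}

test_that("parseStockholm reads interleaved blocks and RF labels", {
  p <- tempfile(fileext = ".sto")
  writeLines(c("# STOCKHOLM 1.0",
               "geneA  AC-GT",
               "geneB  ACAGT",
               "#=GC RF  xx.xx",
               "//"), p)
  prof <- parseStockholm(p, "LysCTT")
  expect_identical(unname(profileRows(prof)), c("AC-GT", "ACAGT"))
  expect_identical(columnLabels(prof), c("1", "2", NA, "3", "4"))
  # interleaved form parses to the identical profile
  p2 <- tempfile(fileext = ".sto")
  writeLines(c("# STOCKHOLM 1.0",
               "geneA  AC-",
               "geneB  ACA",
               "",
               "geneA  GT",
               "geneB  GT",
               "#=GC RF  xx.xx",
               "//"), p2)
  prof2 <- parseStockholm(p2, "LysCTT")
  expect_identical(profileRows(prof2), profileRows(prof))
  expect_identical(columnLabels(prof2), columnLabels(prof))
  # missing terminator and ragged rows are format errors
  p3 <- tempfile(); writeLines(c("# STOCKHOLM 1.0", "geneA AC"), p3)
  expect_error(parseStockholm(p3), "//")
  p4 <- tempfile()
  writeLines(c("# STOCKHOLM 1.0", "geneA AC-GT", "geneB ACGT", "//"), p4)
  expect_error(parseStockholm(p4), "ragged")
  # round-trip through writeStockholm
  p5 <- tempfile(fileext = ".sto")
  writeStockholm(prof, p5)
  prof5 <- parseStockholm(p5, "LysCTT")
  expect_identical(profileRows(prof5), profileRows(prof))
})

test_that("mapPosition projects ungapped positions onto columns", {
  prof <- makeProfile(c(geneA = "AC-GT", geneB = "ACAGT"))
  expect_identical(mapPosition(prof, "geneA", 3)$column, 4L)
  expect_identical(mapPosition(prof, "geneB", 3)$column, 3L)
  # CCA positions past the aligned body get synthetic labels
  expect_identical(mapPosition(prof, "geneA", 5)$label, "CCA1")
  expect_identical(mapPosition(prof, "geneA", 7)$label, "CCA3")
  expect_error(mapPosition(prof, "geneA", 8), "beyond")
  expect_error(mapPosition(prof, "geneC", 1), "not in profile")
  # bijection between non-gap columns and ungapped positions
  for (g in c("geneA", "geneB")) {
    n <- nchar(gsub("-", "", profileRows(prof)[[g]]))
    for (pos in seq_len(n)) {
      col <- mapPosition(prof, g, pos)$column
      expect_identical(columnToPosition(prof, g, col), pos)
    }
  }
  # identical sequences share every column (exhaustive scan)
  prof2 <- makeProfile(c(g1 = "A-CGT", g2 = "A-CGT"))
  for (pos in 1:4)
    expect_identical(mapPosition(prof2, "g1", pos)$column,
                     mapPosition(prof2, "g2", pos)$column)
})

test_that("aggregateIsoacceptor merges isodecoder calls on one column", {
  set.seed(11)
  bodies <- c(paste0(randomSeq(39), "G", randomSeq(20)),
              paste0(randomSeq(39), "G", randomSeq(20)))
  ref <- buildReference(toyGenes(bodies, ids = c("iso1", "iso2"),
                                 iso = "LysCTT"))
  profiles <- ungappedProfiles(ref)
  cands <- data.frame(contig = c("iso1", "iso2"), isoacceptor = "LysCTT",
                      g_position = 40L, peak_position = 41L,
                      score = c(8.1, 9.2), window_start = 41L,
                      window_end = 42L, n_treated = 100L)
  sites <- aggregateIsoacceptor(cands, profiles, ref)
  expect_identical(nrow(sites), 1L)
  expect_identical(sites$n_members, 2L)
  expect_identical(sites$score, 9.2)                # max over members
  expect_identical(sites$label, "40")
  # merging conserves candidates
  expect_identical(sum(sites$n_members), nrow(cands))
  # empty in, empty out
  expect_identical(nrow(aggregateIsoacceptor(cands[0, ], profiles, ref)), 0L)
  # unmatched contig passes through unprojected, with a warning
  refB <- buildReference(toyGenes(randomSeq(60), ids = "other",
                                  iso = "MetCAT"))
  candB <- cands[1, ]; candB$contig <- "other"; candB$isoacceptor <- "MetCAT"
  expect_warning(out <- aggregateIsoacceptor(candB, profiles, refB),
                 "no profile row")
  expect_false(out$projected)
})

test_that("gene renaming leaves isoacceptor-level sites unchanged", {
  set.seed(13)
  bodies <- replicate(3, paste0(randomSeq(39), "G", randomSeq(20)))
  mk <- function(ids) {
    ref <- buildReference(toyGenes(bodies, ids = ids, iso = "AlaAGC"))
    cands <- data.frame(contig = names(contigs(ref)), isoacceptor = "AlaAGC",
                        g_position = 40L, peak_position = 40L, score = 7.7,
                        window_start = 40L, window_end = 40L,
                        n_treated = 60L)
    aggregateIsoacceptor(cands, ungappedProfiles(ref), ref)
  }
  a <- mk(c("g1", "g2", "g3"))
  b <- mk(c("zz1", "zz2", "zz3"))
  expect_identical(a[, c("isoacceptor", "column", "label", "score",
                         "n_members")],
                   b[, c("isoacceptor", "column", "label", "score",
                         "n_members")])
})

test_that("planted sites in several isodecoders merge to one site", {
  set.seed(17)
  bodies <- replicate(5, paste0(randomSeq(45), "G", substr("TCA", 1, 3),
                                randomSeq(12)))
  ref <- buildReference(toyGenes(bodies, ids = sprintf("ly%d", 1:5),
                                 iso = "LysCTT"))
  truth <- plantModifications(ref, position = 46, efficiency = 0.9)
  expect_identical(nrow(truth), 5L)
  libT <- simulateLibrary(ref, truth, "treated",
                          simulationConfig(nReads = 12000), seed = 4)
  libU <- simulateLibrary(ref, NULL, "untreated",
                          simulationConfig(nReads = 12000), seed = 5)
  sT <- countStartSites(filterAlignments(naiveAlign(libT$reads, ref)),
                        "treated")
  sU <- countStartSites(filterAlignments(naiveAlign(libU$reads, ref)),
                        "untreated")
  cands <- callCandidates(scoreTable(sT, sU, ref), threshold = 5)
  sites <- aggregateIsoacceptor(cands, ungappedProfiles(ref), ref)
  expect_identical(nrow(sites), 1L)
  expect_identical(sites$label, "46")
  expect_identical(sites$n_members, 5L)
})
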