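## Chemistry-aware library simulator.
##
## Generative model of the borohydride/aniline protocol on tRNA-like contigs:
## a molecule carrying a modified base cleaves with a per-site efficiency;
## the scission leaves a 3' fragment whose observed read start falls on
## positions N..N+3 of the modified base N (the reverse-transcription stop
## window), a 5' fragment that is mostly lost at adapter ligation, plus
## background fragmentation, full-length molecules, and optional pre-tRNA
## contamination reads drawn from locus/flank junctions on the genome.
## Every emitted read is recorded in a ground-truth log.

.isoacceptorPool <- c(
  "AlaAGC", "AlaTGC", "ArgTCG", "AsnGTT", "AspGTC", "GlyGCC", "HisGTG",
  "LeuTAG", "LysCTT", "MetCAT", "PheGAA", "ProAGG", "SerAGA", "ThrTGT",
  "TrpCCA", "TyrGTA", "ValAAC", "GluTTC", "GlnCTG", "IleAAT", "CysGCA",
  "GlyCCC", "ProCGG", "ArgCCT", "LysTTT", "AlaCGC", "SerGCT", "ThrCGT",
  "ValCAC", "LeuCAA")

#' Generate tRNA-like genes and a surrounding synthetic genome
#'
#' Produces random tRNA-sized gene bodies embedded in a random genome, for
#' exercising the pipeline end to end.  Each distinct body carries a fixed,
#' biologically motivated base context at canonical modification positions:
#' T at 20 (dihydrouridine site), C at 32 (m3C site), G at 46 (the internal
#' m7G site) with non-G bases at 47-49, so that m7G can be planted at the
#' position-46 analogue and off-target m3C/D cleavage at their own analogues.
#'
#' @param nGenes Number of genes (default 20).
#' @param geneLength Gene body length in nt, before the CCA tail (default 76).
#' @param nDistinct Number of distinct sequences; the remaining
#'   \code{nGenes - nDistinct} genes duplicate earlier sequences exactly
#'   (exercising 100\%-identity collapsing).  Default: all distinct.
#' @param pseudogeneFraction Fraction of genes flagged as pseudogenes.
#' @param spacer Length of random genomic spacer between genes (default 200).
#' @param seed Integer seed; the output is a deterministic function of it.
#' @return List with \code{genes} (a data.frame suitable for
#'   \code{\link{buildReference}}, loci 0-based half-open on chromosome
#'   \code{"chrS"}) and \code{genome} (a \link[Biostrings]{DNAStringSet}).
#' @export
simulateTRNAGenes <- function(nGenes = 20L, geneLength = 76L,
                              nDistinct = nGenes, pseudogeneFraction = 0,
                              spacer = 200L, seed = 1L) {
  stopifnot(nDistinct >= 1L, nDistinct <= nGenes, geneLength >= 10L)
  set.seed(seed)
  motif <- c(`20` = "T", `32` = "C", `46` = "G", `47` = "T", `48` = "C",
             `49` = "A")
  makeBody <- function() {
    b <- sample(c("A", "C", "G", "T"), geneLength, replace = TRUE)
    at <- as.integer(names(motif))
    ok <- at <= geneLength
    b[at[ok]] <- motif[ok]
    paste(b, collapse = "")
  }
  bodies <- character(0)
  while (length(bodies) < nDistinct)
    bodies <- unique(c(bodies, replicate(nDistinct - length(bodies) + 1L,
                                         makeBody())))
  bodies <- bodies[seq_len(nDistinct)]
  assign_ <- c(seq_len(nDistinct),
               if (nGenes > nDistinct)
                 sample.int(nDistinct, nGenes - nDistinct, replace = TRUE))
  pool <- .isoacceptorPool
  if (nDistinct > length(pool))
    pool <- paste0(rep(pool, length.out = nDistinct), "_",
                   seq_len(nDistinct))
  isoOfBody <- pool[seq_len(nDistinct)]
  pseudo <- runif(nGenes) < pseudogeneFraction
  chrom <- "chrS"
  spacers <- replicate(nGenes + 1L, paste(
    sample(c("A", "C", "G", "T"), spacer, replace = TRUE), collapse = ""))
  genomeSeq <- spacers[1L]
  startv <- integer(nGenes)
  for (i in seq_len(nGenes)) {
    startv[i] <- nchar(genomeSeq)           # 0-based start
    genomeSeq <- paste0(genomeSeq, bodies[assign_[i]], spacers[i + 1L])
  }
  genes <- data.frame(
    gene_id = sprintf("trna%03d-%s", seq_len(nGenes), isoOfBody[assign_]),
    sequence = bodies[assign_],
    isoacceptor = isoOfBody[assign_],
    source = "db",
    pseudogene = pseudo,
    chrom = chrom,
    start = startv,
    end = startv + geneLength,
    strand = "+",
    stringsAsFactors = FALSE)
  genome <- DNAStringSet(setNames(genomeSeq, chrom))
  list(genes = genes, genome = genome)
}

#' Simulation parameters
#'
#' Bundles and validates the knobs of the library simulator.
#'
#' @param nReads Reads per condition (default 50000).
#' @param readLength Read length after trimming, in nt (default 51, the
#'   small-RNA read length the assay uses).
#' @param stopOffsetProbs Probabilities of the reverse-transcription stop
#'   offset 0..3 relative to the modified position N; the default peaks at
#'   N+1, the nominal beta-elimination scission point.
#' @param pThreePrime,pFivePrime Recovery probability of the 3' and 5'
#'   cleavage fragments.  5' fragments carry a blocked 3' end that defeats
#'   adapter ligation, hence the strong default asymmetry (0.9 vs 0.05).
#' @param backgroundBreakRate Per-base probability of a spontaneous break on
#'   an otherwise intact molecule (default 0.001).
#' @param pretrnaFraction Fraction of reads drawn from pre-tRNA (locus/flank
#'   junction) sequence (default 0).
#' @param errorRate Per-base uniform substitution error rate (default 0; the
#'   signal in this assay is positional, not base-call).
#' @param minFragmentLength Fragments shorter than this are not sequenced
#'   (size selection; default 15).
#' @return A validated list of class \code{"boseq_simconfig"}.
#' @export
simulationConfig <- function(nReads = 50000L, readLength = 51L,
                             stopOffsetProbs = c(`0` = 0.15, `1` = 0.55,
                                                 `2` = 0.20, `3` = 0.10),
                             pThreePrime = 0.9, pFivePrime = 0.05,
                             backgroundBreakRate = 0.001,
                             pretrnaFraction = 0, errorRate = 0,
                             minFragmentLength = 15L) {
  stopifnot(nReads >= 1L, readLength >= 1L, length(stopOffsetProbs) == 4L,
            all(stopOffsetProbs >= 0), abs(sum(stopOffsetProbs) - 1) < 1e-8,
            pThreePrime >= 0, pThreePrime <= 1, pFivePrime >= 0,
            pFivePrime <= 1, backgroundBreakRate >= 0,
            backgroundBreakRate <= 1, pretrnaFraction >= 0,
            pretrnaFraction <= 1, errorRate >= 0, errorRate < 1,
            minFragmentLength >= 1L)
  structure(list(nReads = as.integer(nReads),
                 readLength = as.integer(readLength),
                 stopOffsetProbs = unname(stopOffsetProbs),
                 pThreePrime = pThreePrime, pFivePrime = pFivePrime,
                 backgroundBreakRate = backgroundBreakRate,
                 pretrnaFraction = pretrnaFraction, errorRate = errorRate,
                 minFragmentLength = as.integer(minFragmentLength)),
            class = "boseq_simconfig")
}

.modBase <- c(m7G = "G", m3C = "C", D = "T")

.checkTruth <- function(ref, truth) {
  req <- c("contig", "position", "mod_type", "efficiency")
  miss <- setdiff(req, names(truth))
  if (length(miss))
    stop("truth table lacks column(s): ", paste(miss, collapse = ", "))
  if (!all(truth$mod_type %in% names(.modBase)))
    stop("mod_type must be one of ", paste(names(.modBase), collapse = ", "))
  if (any(truth$efficiency < 0 | truth$efficiency > 1))
    stop("cleavage efficiency must be in [0,1]")
  cs <- as.character(contigs(ref))
  for (i in seq_len(nrow(truth))) {
    ctg <- truth$contig[i]; pos <- truth$position[i]
    if (!ctg %in% names(cs)) stop("unknown contig in truth entry ", i, ": ", ctg)
    if (pos < 1L || pos > nchar(cs[[ctg]]))
      stop("position out of range in truth entry ", i, ": ", ctg, ":", pos)
    have <- substring(cs[[ctg]], pos, pos)
    need <- .modBase[[truth$mod_type[i]]]
    if (have != need)
      stop("cannot plant ", truth$mod_type[i], " at ", ctg, ":", pos,
           " (reference base is ", have, ", needs ", need, ")")
  }
  invisible(truth)
}

#' Plant modified positions on reference contigs
#'
#' Defines the simulator's ground truth: which contigs carry which modified
#' base, where, and with what cleavage efficiency.  Base compatibility is
#' enforced (m7G only at G, m3C only at C, D only at T); planting at an
#' incompatible base is an error naming the offending entry.
#'
#' Either pass an explicit \code{sites} table, or use the rule interface:
#' plant \code{modType} at \code{position} on the given \code{contigs}
#' (default: every non-excluded contig with a compatible base there, or a
#' seeded random subset of \code{nContigs} of them).
#'
#' @param ref A \code{\link{ReferenceSet}}.
#' @param sites Optional data.frame with columns \code{contig},
#'   \code{position} (1-based), \code{mod_type} (\code{m7G}/\code{m3C}/\code{D})
#'   and \code{efficiency}.
#' @param position,modType,efficiency,contigs,nContigs Rule interface, see
#'   Details.
#' @param seed Seed for the \code{nContigs} subset draw.
#' @return The validated truth data.frame.
#' @export
plantModifications <- function(ref, sites = NULL, position = 46L,
                               modType = "m7G", efficiency = 0.8,
                               contigs = NULL, nContigs = NULL, seed = 1L) {
  if (!is.null(sites)) return(.checkTruth(ref, sites))
  cs <- as.character(ref@contigs)
  need <- .modBase[[match.arg(modType, names(.modBase))]]
  if (is.null(contigs)) {
    ok <- names(cs)[substring(cs, position, position) == need &
                      !(names(cs) %in% excludedContigs(ref))]
    if (!is.null(nContigs)) {
      set.seed(seed)
      ok <- sort(sample(ok, nContigs))
    }
    contigs <- ok
  }
  truth <- data.frame(contig = contigs, position = as.integer(position),
                      mod_type = modType, efficiency = efficiency,
                      stringsAsFactors = FALSE)
  .checkTruth(ref, truth)
}

.applyErrors <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  bases <- c("A", "C", "G", "T")
  for (i in seq_along(seqs)) {
    s <- strsplit(seqs[[i]], "")[[1]]
    hit <- which(runif(length(s)) < rate)
    for (j in hit)
      s[j] <- sample(setdiff(bases, s[j]), 1L)
    seqs[[i]] <- paste(s, collapse = "")
  }
  seqs
}

#' Simulate a treated or untreated sequencing library
#'
#' Draws \code{nReads} reads from the generative model of the cleavage
#' chemistry (see the package vignette).  In the treated condition each
#' molecule carrying a modification cleaves with the site's efficiency; the
#' 3' fragment's read start is N + offset with offset drawn from
#' \code{stopOffsetProbs} over 0..3, 3' and 5' fragments are recovered with
#' their respective probabilities, and uncleaved molecules yield full-length
#' or background-break reads.  The untreated condition has no
#' modification-directed cleavage.  A fraction \code{pretrnaFraction} of
#' reads is drawn from locus/flank junction sequence on the unmasked genome.
#' Identical inputs and seed give byte-identical output.
#'
#' @param ref A \code{\link{ReferenceSet}}.
#' @param truth Modification truth table from \code{\link{plantModifications}}
#'   (ignored in the untreated condition; may be \code{NULL}).
#' @param condition \code{"treated"} or \code{"untreated"}.
#' @param config A \code{\link{simulationConfig}}.
#' @param seed Integer seed.
#' @return List of class \code{"boseq_library"} with \code{reads} (named
#'   \link[Biostrings]{DNAStringSet}), \code{truth} (per-read log data.frame
#'   with columns \code{read_id}, \code{contig}, \code{frag_type} in
#'   \{cleaved_3prime, cleaved_5prime, full_length, background, pre_trna\},
#'   \code{cleave_site}, \code{start} (true 1-based start on the contig),
#'   \code{chrom}, \code{gstart} (1-based genomic start, pre-tRNA reads
#'   only)), \code{condition} and \code{seed}.
#' @export
simulateLibrary <- function(ref, truth = NULL,
                            condition = c("treated", "untreated"),
                            config = simulationConfig(), seed = 1L) {
  condition <- match.arg(condition)
  stopifnot(inherits(config, "boseq_simconfig"))
  if (length(contigs(ref)) == 0L) stop("empty reference")
  if (is.null(truth))
    truth <- data.frame(contig = character(), position = integer(),
                        mod_type = character(), efficiency = numeric())
  .checkTruth(ref, truth)
  if (config$pretrnaFraction > 0 &&
      (length(flankRegions(ref)) == 0L || length(refGenome(ref)) == 0L))
    stop("pre-tRNA simulation needs a reference with genome, loci and flanks")

  set.seed(seed)
  nPre <- rbinom(1L, config$nReads, config$pretrnaFraction)
  nMat <- config$nReads - nPre

  cs <- as.character(contigs(ref))
  cl <- nchar(cs)
  nC <- length(cs)
  RL <- config$readLength
  minF <- config$minFragmentLength
  treated <- condition == "treated"

  acc <- vector("list", 0L)
  got <- 0L
  while (got < nMat) {
    m <- as.integer(ceiling((nMat - got) * 1.3)) + 50L
    ci <- sample.int(nC, m, replace = TRUE)
    L <- cl[ci]
    cleave <- rep(NA_integer_, m)
    if (treated && nrow(truth)) {
      for (k in seq_len(nrow(truth))) {
        on <- which(names(cs)[ci] == truth$contig[k])
        if (!length(on)) next
        hit <- on[runif(length(on)) < truth$efficiency[k]]
        cleave[hit] <- pmin(cleave[hit], truth$position[k], na.rm = TRUE)
      }
    }
    off <- sample(0:3, m, replace = TRUE, prob = config$stopOffsetProbs)
    u3 <- runif(m); u5 <- runif(m); ub <- runif(m); upos <- runif(m)
    isClv <- !is.na(cleave)
    pbg <- 1 - (1 - config$backgroundBreakRate)^L
    isBg <- !isClv & ub < pbg
    isFull <- !isClv & !isBg

    rows <- list()
    # 5' cleavage fragment: spans 1..N
    i5 <- which(isClv & u5 < config$pFivePrime & pmin(RL, cleave) >= minF)
    if (length(i5))
      rows$c5 <- data.frame(mol = i5, ci = ci[i5], frag = "cleaved_5prime",
                            site = cleave[i5], start = 1L,
                            len = pmin(RL, cleave[i5]))
    # 3' cleavage fragment: read starts at N + offset
    s3 <- cleave + off
    len3 <- pmin(RL, L - s3 + 1L)
    i3 <- which(isClv & u3 < config$pThreePrime & s3 <= L & len3 >= minF)
    if (length(i3))
      rows$c3 <- data.frame(mol = i3, ci = ci[i3], frag = "cleaved_3prime",
                            site = cleave[i3], start = s3[i3], len = len3[i3])
    # background break: 3' fragment from a uniform position
    sb <- 1L + as.integer(floor(upos * L))
    lenb <- pmin(RL, L - sb + 1L)
    ib <- which(isBg & lenb >= minF)
    if (length(ib))
      rows$bg <- data.frame(mol = ib, ci = ci[ib], frag = "background",
                            site = NA_integer_, start = sb[ib], len = lenb[ib])
    # intact molecule: full-length read (trimmed to read length)
    ifl <- which(isFull)
    if (length(ifl))
      rows$fl <- data.frame(mol = ifl, ci = ci[ifl], frag = "full_length",
                            site = NA_integer_, start = 1L,
                            len = pmin(RL, L[ifl]))
    batch <- do.call(rbind, rows)
    if (is.null(batch) || nrow(batch) == 0L) next
    batch <- batch[order(batch$mol, batch$frag), , drop = FALSE]
    acc[[length(acc) + 1L]] <- batch
    got <- got + nrow(batch)
  }
  mat <- if (nMat > 0L) head(do.call(rbind, acc), nMat) else
    data.frame(mol = integer(), ci = integer(), frag = character(),
               site = integer(), start = integer(), len = integer())

  matSeq <- substr(cs[mat$ci], mat$start, mat$start + mat$len - 1L)
  matLog <- data.frame(
    contig = names(cs)[mat$ci], frag_type = mat$frag,
    cleave_site = mat$site, start = mat$start,
    chrom = NA_character_, gstart = NA_integer_,
    stringsAsFactors = FALSE)

  # pre-tRNA contamination: reads covering the inner edge of a flank on the
  # unmasked genome, i.e. spanning the locus/flank junction
  if (nPre > 0L) {
    fl <- flankRegions(ref)
    gseq <- as.character(refGenome(ref))
    glen <- setNames(nchar(gseq), names(gseq))
    fi <- sample.int(length(fl), nPre, replace = TRUE)
    chromv <- as.character(seqnames(fl))[fi]
    inner <- ifelse(mcols(fl)$side[fi] == "up", end(fl)[fi], start(fl)[fi])
    s0 <- inner - as.integer(floor(runif(nPre) * RL))    # covers `inner`
    s0 <- pmax(s0, 1L)
    s0 <- pmin(s0, glen[chromv] - RL + 1L)
    preSeq <- substr(gseq[chromv], s0, s0 + RL - 1L)
    gidv <- mcols(fl)$gene_id[fi]
    preLog <- data.frame(
      contig = gidv, frag_type = "pre_trna",
      cleave_site = NA_integer_, start = NA_integer_,
      chrom = chromv, gstart = s0, stringsAsFactors = FALSE)
  } else {
    preSeq <- character(0)
    preLog <- matLog[0L, ]
  }

  log <- rbind(matLog, preLog)
  log$read_id <- sprintf("%s|%s|%s|%06d", log$contig, log$frag_type,
                         ifelse(is.na(log$cleave_site), "NA",
                                log$cleave_site), seq_len(nrow(log)))
  log <- log[, c("read_id", "contig", "frag_type", "cleave_site", "start",
                 "chrom", "gstart")]
  seqs <- .applyErrors(c(matSeq, preSeq), config$errorRate)
  reads <- DNAStringSet(setNames(seqs, log$read_id))
  structure(list(reads = reads, truth = log, condition = condition,
                 seed = seed), class = "boseq_library")
}

#' @export
print.boseq_simconfig <- function(x, ...) {
  cat("boseq simulation config:", x$nReads, "reads of", x$readLength, "nt;",
      "offsets", paste(x$stopOffsetProbs, collapse = "/"), "\n")
  invisible(x)
}

#' @export
print.boseq_library <- function(x, ...) {
  cat("boseq", x$condition, "library:", length(x$reads), "reads (seed",
      x$seed, ")\n")
  print(table(x$truth$frag_type))
  invisible(x)
}

#' Write a simulated library to FASTQ and its truth log to TSV
#'
#' Quality strings are constant \code{'I'}.
#'
#' @param lib A library from \code{\link{simulateLibrary}}.
#' @param fastq Output FASTQ path (use a \code{.gz} suffix to compress).
#' @param truthTsv Optional truth-log TSV path.
#' @return Invisibly, the FASTQ path.
#' @export
writeLibrary <- function(lib, fastq, truthTsv = NULL) {
  quals <- BStringSet(vapply(width(lib$reads),
                             function(w) strrep("I", w), character(1)))
  writeXStringSet(lib$reads, fastq, format = "fastq", qualities = quals,
                  compress = grepl("\\.gz$", fastq))
  if (!is.null(truthTsv))
    write.table(lib$truth, truthTsv, sep = "\t", quote = FALSE,
                row.names = FALSE)
  invisible(fastq)
}
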