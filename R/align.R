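## Alignment ingestion, filtering and start-site counting.
##
## Alignments are plain data.frames with columns read_id, contig, start
## (0-based leftmost reference base), end (0-based exclusive) and mapq;
## SAM/BAM goes through Rsamtools/GenomicAlignments, and a naive
## exact-substring aligner covers simulated reads so the pipeline is
## self-contained in tests.

.emptyAlignments <- function() {
  data.frame(read_id = character(), contig = character(), start = integer(),
             end = integer(), mapq = integer(), stringsAsFactors = FALSE)
}

#' Read primary alignments from SAM/BAM
#'
#' Yields primary, mapped alignments only, with coordinates converted to the
#' package's internal 0-based half-open convention.  A \code{.sam} input is
#' converted on the fly.
#'
#' @param path SAM or BAM file.
#' @param ref Optional \code{\link{ReferenceSet}}; alignments to contigs
#'   absent from it are dropped with a warning (or an error when
#'   \code{onUnknownContig = "error"}).
#' @param onUnknownContig \code{"warn"} or \code{"error"}.
#' @return Alignment data.frame (read_id, contig, start, end, mapq).
#' @export
readAlignments <- function(path, ref = NULL,
                           onUnknownContig = c("warn", "error")) {
  onUnknownContig <- match.arg(onUnknownContig)
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    path <- asBam(path, destination = dest, overwrite = TRUE,
                  indexDestination = FALSE)
  }
  param <- ScanBamParam(
    what = c("qname", "mapq"),
    flag = scanBamFlag(isUnmappedQuery = FALSE, isSecondaryAlignment = FALSE,
                       isSupplementaryAlignment = FALSE))
  ga <- readGAlignments(path, param = param)
  aln <- data.frame(
    read_id = mcols(ga)$qname,
    contig = as.character(seqnames(ga)),
    start = start(ga) - 1L,
    end = end(ga),                      # 1-based incl == 0-based excl
    mapq = as.integer(mcols(ga)$mapq),
    stringsAsFactors = FALSE)
  if (!is.null(ref)) {
    known <- aln$contig %in% names(contigs(ref))
    if (any(!known)) {
      msg <- paste0(sum(!known), " alignment(s) to contigs absent from the ",
                    "reference")
      if (onUnknownContig == "error") stop(msg)
      warning(msg, "; skipped")
      aln <- aln[known, , drop = FALSE]
    }
  }
  aln
}

#' Exact-substring alignment of reads against a small reference
#'
#' Places each read at the position where it occurs verbatim in a contig
#' (sense strand only; the library protocol is strand-preserving).  A unique
#' occurrence gets MAPQ 30; multiple equally good occurrences get MAPQ 0 and
#' the lexicographically first placement; reads with no exact occurrence are
#' unaligned and omitted.  This is a deterministic test-scale stand-in for an
#' external aligner, adequate because simulated reads are error-free
#' substrings by construction.
#'
#' @param reads Named \link[Biostrings]{DNAStringSet} (or named character).
#' @param subject A \code{\link{ReferenceSet}} (its contigs are used) or a
#'   \code{DNAStringSet} (e.g. the unmasked genome).
#' @return Alignment data.frame (read_id, contig, start, end, mapq).
#' @export
naiveAlign <- function(reads, subject) {
  if (is(subject, "ReferenceSet")) subject <- contigs(subject)
  subj <- as.character(subject)
  subj <- subj[order(names(subj))]
  rs <- as.character(reads)
  if (length(rs) == 0L) return(.emptyAlignments())
  rw <- nchar(rs)
  widths <- sort(unique(rw))
  widths <- widths[widths >= 1L & widths <= max(nchar(subj))]
  seqL <- list(); ctgL <- list(); posL <- list()
  k <- 0L
  for (w in widths) {
    for (ctg in names(subj)) {
      L <- nchar(subj[[ctg]])
      if (L < w) next
      st <- seq_len(L - w + 1L)
      k <- k + 1L
      seqL[[k]] <- substring(subj[[ctg]], st, st + w - 1L)
      ctgL[[k]] <- rep(ctg, length(st))
      posL[[k]] <- st
    }
  }
  seqv <- unlist(seqL, use.names = FALSE)
  ctgv <- unlist(ctgL, use.names = FALSE)
  posv <- unlist(posL, use.names = FALSE)
  dup <- duplicated(seqv) | duplicated(seqv, fromLast = TRUE)
  hit <- match(rs, seqv)
  ok <- !is.na(hit)
  data.frame(
    read_id = names(rs)[ok],
    contig = ctgv[hit[ok]],
    start = posv[hit[ok]] - 1L,
    end = posv[hit[ok]] - 1L + rw[ok],
    mapq = ifelse(dup[hit[ok]], 0L, 30L),
    stringsAsFactors = FALSE)
}

#' Remove pre-tRNA reads using genome flank alignments
#'
#' Pre-tRNA transcripts retain genomic leader/trailer sequence; their reads
#' align into the flank intervals around the gene loci on the unmasked
#' genome.  Every read whose genome alignment overlaps any flank by at least
#' one base is flagged, and flagged reads are removed from the tRNA-contig
#' alignments.
#'
#' @param trnaAln Alignments against the tRNA contigs.
#' @param genomeAln Alignments of the same reads against the unmasked genome.
#' @param flanks Flank \link[GenomicRanges]{GRanges}
#'   (\code{\link{flankRegions}}).
#' @return List with \code{alignments} (surviving tRNA alignments) and
#'   \code{removed} (character vector of removed read names).
#' @export
subtractPretrna <- function(trnaAln, genomeAln, flanks) {
  if (length(flanks) == 0L || nrow(genomeAln) == 0L)
    return(list(alignments = trnaAln, removed = character(0)))
  gr <- GRanges(genomeAln$contig,
                IRanges(genomeAln$start + 1L, genomeAln$end))
  hits <- findOverlaps(gr, flanks, minoverlap = 1L, ignore.strand = TRUE)
  removed <- sort(unique(genomeAln$read_id[queryHits(hits)]))
  list(alignments = trnaAln[!trnaAln$read_id %in% removed, , drop = FALSE],
       removed = removed)
}

#' Apply MAPQ, contig-exclusion and duplicate filters
#'
#' Implements the analysis filters: drop alignments with mapping quality
#' below \code{mapqMin} (default 1, discarding multi-mappers), drop
#' alignments to excluded contigs (pseudogenes, mitochondrial), and
#' optionally collapse identical duplicates (same contig, start and end; and
#' sequence, when a \code{sequence} column is present) to one representative.
#' Deduplication defaults off: the simulator has no PCR duplication, but it
#' is recommended for real libraries.
#'
#' @param aln Alignment data.frame.
#' @param mapqMin Minimum MAPQ kept (default 1).
#' @param exclude Contig ids to drop (\code{\link{excludedContigs}}).
#' @param dedup Collapse identical duplicates.
#' @return Filtered alignment data.frame.
#' @export
filterAlignments <- function(aln, mapqMin = 1L, exclude = character(0),
                             dedup = FALSE) {
  aln <- aln[aln$mapq >= mapqMin & !aln$contig %in% exclude, , drop = FALSE]
  if (dedup && nrow(aln)) {
    keyCols <- intersect(c("contig", "start", "end", "sequence"), names(aln))
    key <- do.call(paste, c(aln[keyCols], sep = "\r"))
    aln <- aln[!duplicated(key), , drop = FALSE]
  }
  aln
}

#' StartCountTable: per-position fragment start-site counts
#'
#' One per condition.  \code{counts} holds the raw per-(contig, position)
#' start counts (1-based positions) with a \code{supported} flag marking
#' cells meeting the minimum read support; \code{totals} is the total number
#' of aligned reads per contig, the denominator of the cleavage ratio, which
#' always includes reads at unsupported cells.
#'
#' @slot condition \code{"treated"} or \code{"untreated"}.
#' @slot counts data.frame(contig, pos, count, supported).
#' @slot totals Named integer vector of per-contig aligned-read totals.
#' @slot minSupport The support threshold applied (default 10).
#' @export
setClass("StartCountTable",
  slots = c(condition = "character", counts = "data.frame",
            totals = "integer", minSupport = "numeric"))

setValidity("StartCountTable", function(object) {
  msg <- character()
  cts <- object@counts
  if (!all(c("contig", "pos", "count", "supported") %in% names(cts)))
    msg <- c(msg, "counts needs columns contig, pos, count, supported")
  else {
    if (any(cts$count < 0)) msg <- c(msg, "counts must be non-negative")
    bySum <- tapply(cts$count, cts$contig, sum)
    tot <- object@totals[names(bySum)]
    if (any(is.na(tot)) || any(bySum != tot))
      msg <- c(msg, "per-contig counts must sum to totals")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "StartCountTable", function(object) {
  cat("StartCountTable (", object@condition, "): ",
      sum(object@counts$count), " reads over ", nrow(object@counts),
      " start cells on ", length(object@totals), " contigs; min support ",
      object@minSupport, "\n", sep = "")
})

#' @rdname StartCountTable
#' @param x A \code{StartCountTable}.
#' @export
setGeneric("startCounts",
           function(x, zeroUnsupported = TRUE) standardGeneric("startCounts"))
#' @describeIn StartCountTable Start counts; with \code{zeroUnsupported}
#'   (default) cells below the support threshold are zeroed, as in scoring.
#' @param zeroUnsupported Zero cells below the support threshold.
#' @export
setMethod("startCounts", "StartCountTable", function(x, zeroUnsupported = TRUE) {
  cts <- x@counts
  if (zeroUnsupported) cts$count[!cts$supported] <- 0L
  cts
})

#' @rdname StartCountTable
#' @export
setGeneric("libTotals", function(x) standardGeneric("libTotals"))
#' @describeIn StartCountTable Per-contig aligned-read totals.
#' @export
setMethod("libTotals", "StartCountTable", function(x) x@totals)

#' @rdname StartCountTable
#' @export
setGeneric("conditionOf", function(x) standardGeneric("conditionOf"))
#' @describeIn StartCountTable Condition label.
#' @export
setMethod("conditionOf", "StartCountTable", function(x) x@condition)

#' Tabulate fragment start sites per contig position
#'
#' Counts, for every (contig, position) cell, the number of alignments whose
#' start is that position.  Cells supported by fewer than \code{minSupport}
#' reads are flagged unsupported and treated as zero in scoring, but their
#' reads still count towards the per-contig total (the cleavage-ratio
#' denominator is total aligned reads, not the sum of retained starts).
#'
#' @param aln Filtered alignment data.frame.
#' @param condition \code{"treated"} or \code{"untreated"}.
#' @param minSupport Minimum reads per start-site cell (default 10).
#' @return A \code{\link{StartCountTable}}.
#' @export
countStartSites <- function(aln, condition = c("treated", "untreated"),
                            minSupport = 10L) {
  condition <- match.arg(condition)
  if (nrow(aln)) {
    key <- paste(aln$contig, aln$start, sep = "\r")
    tab <- table(key)
    parts <- strsplit(names(tab), "\r", fixed = TRUE)
    cts <- data.frame(
      contig = vapply(parts, `[`, character(1), 1L),
      pos = as.integer(vapply(parts, `[`, character(1), 2L)) + 1L,
      count = as.integer(tab),
      stringsAsFactors = FALSE)
    cts <- cts[order(cts$contig, cts$pos), , drop = FALSE]
    rownames(cts) <- NULL
    totals <- vapply(split(cts$count, cts$contig), sum, numeric(1))
    totals <- setNames(as.integer(totals), names(totals))
  } else {
    cts <- data.frame(contig = character(), pos = integer(),
                      count = integer(), stringsAsFactors = FALSE)
    totals <- setNames(integer(0), character(0))
  }
  cts$supported <- cts$count >= minSupport
  new("StartCountTable", condition = condition, counts = cts,
      totals = totals, minSupport = as.numeric(minSupport))
}

#' Per-contig read-depth profiles
#'
#' Depth at position p is the number of alignments covering p
#' (\code{start <= p < end}).  Returned unnormalised; normalisation happens
#' in reporting.
#'
#' @param aln Filtered alignment data.frame.
#' @param ref A \code{\link{ReferenceSet}} (fixes contig lengths so profiles
#'   cover every position).
#' @return Named list of integer depth vectors, one per contig, 1-based.
#' @export
coverageProfile <- function(aln, ref) {
  lens <- setNames(width(contigs(ref)), names(contigs(ref)))
  out <- lapply(lens, function(L) integer(L))
  if (nrow(aln)) {
    aln <- aln[aln$contig %in% names(lens), , drop = FALSE]
    gr <- GRanges(aln$contig, IRanges(aln$start + 1L, aln$end),
                  seqlengths = lens)
    cov <- coverage(gr)
    for (ctg in names(cov)) out[[ctg]] <- as.integer(cov[[ctg]])
  }
  out
}
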