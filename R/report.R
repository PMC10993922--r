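## Reporting (coverage heatmap matrices, per-isoacceptor score profiles)
## and the end-to-end pipeline with its reproducibility manifest.

#' Normalised coverage heatmap matrix per isoacceptor
#'
#' Projects per-contig read-depth profiles onto alignment columns, sums the
#' member contigs of each isoacceptor, and normalises.  Columns past a
#' profile's aligned body hold the CCA tail (body width + 1..3).
#'
#' @param coverages Named list of per-contig depth vectors
#'   (\code{\link{coverageProfile}}).
#' @param profiles List of \code{\link{AlignmentProfile}}s.
#' @param ref A \code{\link{ReferenceSet}}.
#' @param normalization \code{"row_max"} (each row divided by its maximum;
#'   zero rows stay zero) or \code{"cpm"} (divided by library size times
#'   1e-6; requires \code{librarySize}).
#' @param librarySize Total reads in the condition (cpm only).
#' @param condition Optional condition tag stored as an attribute.
#' @return Numeric matrix, rows = isoacceptors, columns = alignment columns
#'   (+3 CCA columns); attributes \code{normalization} and \code{condition}.
#' @export
heatmapMatrix <- function(coverages, profiles, ref,
                          normalization = c("row_max", "cpm"),
                          librarySize = NULL, condition = NA_character_) {
  normalization <- match.arg(normalization)
  if (normalization == "cpm" && is.null(librarySize))
    stop("cpm normalization needs librarySize")
  cs <- as.character(contigs(ref))
  isoRows <- sort(vapply(profiles, function(p) p@isoacceptor, character(1)))
  maxW <- max(vapply(profiles, function(p)
    if (length(profileRows(p))) nchar(profileRows(p)[[1L]]) else 0L,
    integer(1)))
  mat <- matrix(0, nrow = length(isoRows), ncol = maxW + 3L,
                dimnames = list(isoRows,
                                c(as.character(seq_len(maxW)),
                                  paste0("CCA", 1:3))))
  for (ctg in names(coverages)) {
    if (!ctg %in% names(cs)) next
    m <- .matchProfileRow(cs[[ctg]], profiles)
    if (is.null(m)) next
    iso <- m$profile@isoacceptor
    ch <- strsplit(profileRows(m$profile)[[m$geneId]], "")[[1]]
    nongap <- which(!(ch %in% .GAPCHARS))
    w <- length(ch)
    depth <- coverages[[ctg]]
    bodyLen <- length(nongap)
    cols <- c(nongap, w + 1:3)[seq_along(depth)]
    keep <- !is.na(cols)
    add <- tapply(depth[keep], cols[keep], sum)
    mat[iso, as.integer(names(add))] <-
      mat[iso, as.integer(names(add))] + add
  }
  if (normalization == "row_max") {
    rm_ <- apply(mat, 1L, max)
    nz <- rm_ > 0
    mat[nz, ] <- mat[nz, , drop = FALSE] / rm_[nz]
  } else {
    mat <- mat / (librarySize * 1e-6)
  }
  attr(mat, "normalization") <- normalization
  attr(mat, "condition") <- condition
  mat
}

#' Plot a coverage heatmap
#'
#' Thin optional wrapper over \pkg{pheatmap}; the exported matrix is the
#' analysis artifact, the image is presentation only.
#'
#' @param mat Matrix from \code{\link{heatmapMatrix}}.
#' @param ... Passed to \code{\link[pheatmap]{pheatmap}}.
#' @export
plotHeatmap <- function(mat, ...) {
  if (!requireNamespace("pheatmap", quietly = TRUE))
    stop("plotHeatmap needs the pheatmap package")
  pheatmap::pheatmap(mat, cluster_rows = FALSE, cluster_cols = FALSE, ...)
}

#' Export per-isoacceptor cleavage-score profiles
#'
#' Long-format, plot-ready table of scores with their projected columns and
#' candidate flags; one row per (contig, position).
#'
#' @param tbl Score table from \code{\link{scoreTable}}.
#' @param profiles List of \code{\link{AlignmentProfile}}s.
#' @param ref A \code{\link{ReferenceSet}}.
#' @param candidates Optional candidate table; flagged in
#'   \code{is_candidate} (at the candidate guanosine position).
#' @param path Optional TSV output path.
#' @return data.frame (isoacceptor, contig, position, column, label, score,
#'   n_treated, n_untreated, is_candidate), sorted by (isoacceptor, contig,
#'   position); written to \code{path} when given.
#' @export
scoreProfileExport <- function(tbl, profiles, ref, candidates = NULL,
                               path = NULL) {
  cs <- as.character(contigs(ref))
  out <- tbl[, c("isoacceptor", "contig", "position", "score", "n_treated",
                 "n_untreated")]
  out$column <- NA_integer_
  out$label <- NA_character_
  for (ctg in unique(out$contig)) {
    m <- .matchProfileRow(cs[[ctg]], profiles)
    if (is.null(m)) next
    ch <- strsplit(profileRows(m$profile)[[m$geneId]], "")[[1]]
    nongap <- which(!(ch %in% .GAPCHARS))
    lab <- columnLabels(m$profile)
    idx <- out$contig == ctg
    pos <- out$position[idx]
    col <- rep(NA_integer_, length(pos))
    inBody <- pos <= length(nongap)
    col[inBody] <- nongap[pos[inBody]]
    labv <- rep(NA_character_, length(pos))
    labv[inBody] <- if (length(lab)) lab[col[inBody]] else
      as.character(col[inBody])
    ccaOff <- pos - length(nongap)
    inCCA <- ccaOff >= 1L & ccaOff <= 3L
    labv[inCCA] <- paste0("CCA", ccaOff[inCCA])
    out$column[idx] <- col
    out$label[idx] <- labv
    out$isoacceptor[idx] <- m$profile@isoacceptor
  }
  out$is_candidate <- FALSE
  if (!is.null(candidates) && nrow(candidates))
    out$is_candidate <- paste(out$contig, out$position) %in%
      paste(candidates$contig, candidates$g_position)
  out <- out[order(out$isoacceptor, out$contig, out$position),
             c("isoacceptor", "contig", "position", "column", "label",
               "score", "n_treated", "n_untreated", "is_candidate")]
  rownames(out) <- NULL
  if (!is.null(path))
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  out
}

#' Read a ReferenceSet written by writeReference
#'
#' @param dir Directory holding \code{reference.fa}, \code{members.tsv} and
#'   optionally \code{flanks.bed} / \code{genome_masked.fa}.
#' @return A \code{\link{ReferenceSet}} (gene loci are not round-tripped).
#' @export
readReference <- function(dir) {
  cs <- readDNAStringSet(file.path(dir, "reference.fa"))
  names(cs) <- sub("\\s.*$", "", names(cs))
  mem <- read.delim(file.path(dir, "members.tsv"), stringsAsFactors = FALSE)
  members <- split(mem$gene_id, mem$contig)[names(cs)]
  iso <- setNames(mem$isoacceptor[!duplicated(mem$contig)],
                  mem$contig[!duplicated(mem$contig)])[names(cs)]
  excl <- unique(mem$contig[mem$excluded])
  flanks <- GRanges()
  bedPath <- file.path(dir, "flanks.bed")
  if (file.exists(bedPath) && file.size(bedPath) > 0) {
    bed <- read.delim(bedPath, header = FALSE, stringsAsFactors = FALSE)
    flanks <- GRanges(bed$V1, IRanges(bed$V2 + 1L, bed$V3), strand = bed$V6)
    mcols(flanks)$gene_id <- sub("_(up|down)$", "", bed$V4)
    mcols(flanks)$side <- sub("^.*_", "", bed$V4)
  }
  mg <- DNAStringSet()
  mgPath <- file.path(dir, "genome_masked.fa")
  if (file.exists(mgPath)) mg <- readDNAStringSet(mgPath)
  new("ReferenceSet", contigs = cs, members = members, isoacceptor = iso,
      excluded = excl, loci = GRanges(), flanks = flanks,
      genome = DNAStringSet(), maskedGenome = mg)
}

.writeCounts <- function(sct, path) {
  cts <- startCounts(sct, zeroUnsupported = FALSE)
  cts$total <- libTotals(sct)[cts$contig]
  cts$condition <- conditionOf(sct)
  cts$min_support <- sct@minSupport
  write.table(cts, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a start-count TSV back into a StartCountTable
#'
#' Inverse of the count export written by \code{\link{runPipeline}} (columns
#' contig, pos, count, supported, total, condition, min_support).
#'
#' @param path TSV path.
#' @return A \code{\link{StartCountTable}}.
#' @export
readStartCounts <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  tot <- d[!duplicated(d$contig), c("contig", "total")]
  new("StartCountTable", condition = d$condition[1L],
      counts = d[, c("contig", "pos", "count", "supported")],
      totals = setNames(as.integer(tot$total), tot$contig),
      minSupport = as.numeric(d$min_support[1L]))
}

.writeBedGraph <- function(coverages, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (ctg in names(coverages)) {
    d <- coverages[[ctg]]
    r <- rle(d)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths            # 0-based
    keep <- r$values > 0
    if (any(keep))
      writeLines(sprintf("%s\t%d\t%d\t%d", ctg, starts[keep], ends[keep],
                         r$values[keep]), con)
  }
  invisible(path)
}

.stageLog <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, paste0(...)))
}

#' Run the full pipeline on a simulated or file-based study
#'
#' Orchestrates reference construction, (optionally) library simulation,
#' alignment, the filter cascade, start-site counting, cleavage scoring,
#' candidate calling, isoacceptor projection and report export, writing all
#' artifacts plus a YAML manifest of resolved parameters and output
#' checksums.  Everything is a deterministic function of the inputs and
#' \code{seed}: re-running with the same arguments reproduces byte-identical
#' files.
#'
#' In simulation mode (default) a ground-truthed study is generated with
#' \code{\link{simulateTRNAGenes}} and m7G planted at \code{plantPosition}
#' on \code{nPlant} contigs.  In file mode supply \code{refDir} (from
#' \code{\link{writeReference}}) and \code{treated}/\code{untreated} SAM/BAM
#' paths.
#'
#' @param outDir Output directory.
#' @param seed Integer seed for every random draw.
#' @param simulate Generate the study instead of reading files.
#' @param nGenes,geneLength,nDistinct Simulated gene set, see
#'   \code{\link{simulateTRNAGenes}}.
#' @param nPlant Number of contigs carrying a planted m7G (default half).
#' @param plantPosition Planted position (default 46).
#' @param efficiency Planted cleavage efficiency (default 0.8).
#' @param extraSites Optional extra truth rows (e.g. m3C/D off-targets),
#'   rbound to the planted m7G truth.
#' @param config \code{\link{simulationConfig}} for both libraries.
#' @param refDir,treated,untreated File mode inputs.
#' @param alpha Pseudocount (default 0.5).
#' @param threshold Calling threshold (default 6.5).
#' @param minSupport Minimum reads per start cell (default 10).
#' @param mapqMin Minimum MAPQ (default 1).
#' @param dedup Collapse duplicate alignments (default off).
#' @return Invisibly, a list with the reference, truth, count tables, score
#'   table, candidates, isoacceptor sites, heatmap matrix, manifest and
#'   output paths.
#' @export
runPipeline <- function(outDir, seed = 1L, simulate = TRUE,
                        nGenes = 20L, geneLength = 76L, nDistinct = nGenes,
                        nPlant = max(1L, nGenes %/% 2L), plantPosition = 46L,
                        efficiency = 0.8, extraSites = NULL,
                        config = simulationConfig(),
                        refDir = NULL, treated = NULL, untreated = NULL,
                        alpha = 0.5, threshold = 6.5, minSupport = 10L,
                        mapqMin = 1L, dedup = FALSE) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  paths <- c()
  params <- list(seed = as.integer(seed), simulate = simulate, alpha = alpha,
                 threshold = threshold, minSupport = as.integer(minSupport),
                 mapqMin = as.integer(mapqMin), dedup = dedup)

  if (simulate) {
    params <- c(params, list(
      nGenes = as.integer(nGenes), geneLength = as.integer(geneLength),
      nDistinct = as.integer(nDistinct), nPlant = as.integer(nPlant),
      plantPosition = as.integer(plantPosition), efficiency = efficiency,
      nReads = config$nReads, readLength = config$readLength,
      stopOffsetProbs = config$stopOffsetProbs,
      pThreePrime = config$pThreePrime, pFivePrime = config$pFivePrime,
      backgroundBreakRate = config$backgroundBreakRate,
      pretrnaFraction = config$pretrnaFraction,
      errorRate = config$errorRate))
    sim <- simulateTRNAGenes(nGenes, geneLength, nDistinct, seed = seed)
    ref <- buildReference(sim$genes, sim$genome)
    .stageLog("build-ref", length(contigs(ref)), " contigs from ", nGenes,
              " genes; ", length(excludedContigs(ref)), " excluded")
    truth <- plantModifications(ref, position = plantPosition,
                                efficiency = efficiency, nContigs = nPlant,
                                seed = seed + 1L)
    if (!is.null(extraSites)) truth <- .checkTruth(ref, rbind(truth, extraSites))
    .stageLog("plant", nrow(truth), " modified sites")
    libT <- simulateLibrary(ref, truth, "treated", config, seed = seed + 2L)
    libU <- simulateLibrary(ref, NULL, "untreated", config, seed = seed + 3L)
    .stageLog("simulate", length(libT$reads), " treated + ",
              length(libU$reads), " untreated reads")
    alns <- lapply(list(treated = libT, untreated = libU), function(lib) {
      a <- naiveAlign(lib$reads, ref)
      if (config$pretrnaFraction > 0) {
        g <- naiveAlign(lib$reads, refGenome(ref))
        s <- subtractPretrna(a, g, flankRegions(ref))
        .stageLog("pre-trna", length(s$removed), " reads removed (",
                  lib$condition, ")")
        s$alignments
      } else a
    })
  } else {
    if (is.null(refDir)) stop("file mode needs --ref (refDir)")
    if (is.null(treated)) stop("file mode needs --treated")
    if (is.null(untreated)) stop("file mode needs --untreated")
    ref <- readReference(refDir)
    truth <- NULL
    libT <- libU <- NULL
    alns <- list(treated = readAlignments(treated, ref),
                 untreated = readAlignments(untreated, ref))
  }

  filt <- lapply(alns, filterAlignments, mapqMin = mapqMin,
                 exclude = excludedContigs(ref), dedup = dedup)
  .stageLog("filter", nrow(alns$treated), " -> ", nrow(filt$treated),
            " treated; ", nrow(alns$untreated), " -> ",
            nrow(filt$untreated), " untreated alignments")
  sctT <- countStartSites(filt$treated, "treated", minSupport)
  sctU <- countStartSites(filt$untreated, "untreated", minSupport)
  tbl <- scoreTable(sctT, sctU, ref, alpha = alpha)
  cands <- callCandidates(tbl, threshold = threshold)
  .stageLog("score", nrow(cands), " candidate site(s) at threshold ",
            threshold)
  profiles <- ungappedProfiles(ref)
  sites <- aggregateIsoacceptor(cands, profiles, ref)
  covT <- coverageProfile(filt$treated, ref)
  hm <- heatmapMatrix(covT, profiles, ref, "row_max", condition = "treated")

  # ---- artifacts -----------------------------------------------------------
  refPaths <- writeReference(ref, file.path(outDir, "ref"))
  paths <- c(paths, refPaths)
  if (simulate) {
    paths[["treated_fastq"]] <- file.path(outDir, "treated.fastq")
    paths[["untreated_fastq"]] <- file.path(outDir, "untreated.fastq")
    paths[["treated_truth"]] <- file.path(outDir, "treated_truth.tsv")
    paths[["untreated_truth"]] <- file.path(outDir, "untreated_truth.tsv")
    writeLibrary(libT, paths[["treated_fastq"]], paths[["treated_truth"]])
    writeLibrary(libU, paths[["untreated_fastq"]], paths[["untreated_truth"]])
    paths[["planted_sites"]] <- file.path(outDir, "planted_sites.tsv")
    write.table(truth, paths[["planted_sites"]], sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  paths[["counts_treated"]] <- file.path(outDir, "counts_treated.tsv")
  paths[["counts_untreated"]] <- file.path(outDir, "counts_untreated.tsv")
  .writeCounts(sctT, paths[["counts_treated"]])
  .writeCounts(sctU, paths[["counts_untreated"]])
  paths[["scores"]] <- file.path(outDir, "scores.tsv")
  write.table(tbl, paths[["scores"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  paths[["candidates"]] <- file.path(outDir, "candidates.tsv")
  write.table(cands, paths[["candidates"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  paths[["sites"]] <- file.path(outDir, "sites.tsv")
  write.table(sites, paths[["sites"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  paths[["heatmap"]] <- file.path(outDir, "heatmap_treated.tsv")
  write.table(data.frame(isoacceptor = rownames(hm), hm, check.names = FALSE),
              paths[["heatmap"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  paths[["profiles"]] <- file.path(outDir, "score_profiles.tsv")
  scoreProfileExport(tbl, profiles, ref, cands, paths[["profiles"]])
  paths[["coverage_bedgraph"]] <- file.path(outDir, "coverage_treated.bedgraph")
  .writeBedGraph(covT, paths[["coverage_bedgraph"]])

  manifest <- list(parameters = params,
                   outputs = as.list(setNames(unname(md5sum(unname(paths))),
                                              names(paths))))
  manifestPath <- file.path(outDir, "manifest.yaml")
  yaml::write_yaml(manifest, manifestPath)
  .stageLog("done", length(paths), " artifacts; manifest ", manifestPath)

  invisible(list(ref = ref, truth = truth, counts = list(treated = sctT,
                 untreated = sctU), scores = tbl, candidates = cands,
                 sites = sites, heatmap = hm, manifest = manifest,
                 manifestPath = manifestPath, paths = paths))
}
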