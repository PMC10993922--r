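## Reference construction: CCA-tailed mature tRNA contigs collapsed at 100%
## identity, an N-masked genome, and flank intervals for pre-tRNA filtering.
##
## Coordinate conventions: gene tables (the on-disk interface) use 0-based
## half-open loci; everything held in GRanges is 1-based inclusive, and all
## user-facing reports are 1-based (so that "G46" means the 46th base).

#' ReferenceSet: the tRNA mapping reference
#'
#' Container for the mapping reference used throughout the pipeline:
#' CCA-tailed mature tRNA contigs (one per distinct sequence after collapsing
#' identical genes), the gene membership of each contig, isoacceptor labels,
#' the set of contigs excluded from analysis (all members pseudogene or
#' mitochondrial), gene loci and flank intervals on the genome, and the
#' (optionally masked) genome itself.
#'
#' @slot contigs A \link[Biostrings]{DNAStringSet} of CCA-tailed contigs.
#' @slot members Named list mapping contig id to the character vector of
#'   collapsed gene ids.
#' @slot isoacceptor Named character vector, contig id to isoacceptor label
#'   (amino acid + anticodon, e.g. \code{"LysCTT"}).
#' @slot excluded Character vector of contig ids flagged pseudogene/mito.
#' @slot loci \link[GenomicRanges]{GRanges} of gene loci (may be empty);
#'   \code{mcols()$gene_id} names the gene.
#' @slot flanks \link[GenomicRanges]{GRanges} of flank intervals used for
#'   pre-tRNA filtering (may be empty).
#' @slot genome Unmasked genome as a \code{DNAStringSet} (may be empty).
#' @slot maskedGenome Genome with tRNA loci replaced by N (may be empty).
#'
#' @seealso \code{\link{buildReference}}
#' @export
setClass("ReferenceSet",
  slots = c(
    contigs      = "DNAStringSet",
    members      = "list",
    isoacceptor  = "character",
    excluded     = "character",
    loci         = "GRanges",
    flanks       = "GRanges",
    genome       = "DNAStringSet",
    maskedGenome = "DNAStringSet"
  )
)

setValidity("ReferenceSet", function(object) {
  msg <- character()
  cs <- as.character(object@contigs)
  if (length(cs)) {
    if (!all(substring(cs, nchar(cs) - 2L) == "CCA"))
      msg <- c(msg, "every contig sequence must end with 'CCA'")
    if (anyDuplicated(cs))
      msg <- c(msg, "contig sequences must be distinct")
  }
  if (!identical(sort(names(object@members)), sort(names(object@contigs))))
    msg <- c(msg, "members must be named by contig id")
  allMembers <- unlist(object@members, use.names = FALSE)
  if (anyDuplicated(allMembers))
    msg <- c(msg, "member gene lists must be disjoint")
  if (length(object@isoacceptor) &&
      !all(names(object@isoacceptor) %in% names(object@contigs)))
    msg <- c(msg, "isoacceptor labels must be named by contig id")
  if (!all(object@excluded %in% names(object@contigs)))
    msg <- c(msg, "excluded ids must be contig ids")
  if (length(msg)) msg else TRUE
})

#' @describeIn ReferenceSet Number of contigs.
#' @param x,object A \code{ReferenceSet}.
#' @export
setMethod("length", "ReferenceSet", function(x) length(x@contigs))

setMethod("show", "ReferenceSet", function(object) {
  cat("ReferenceSet with", length(object@contigs), "contigs (",
      length(unlist(object@members, use.names = FALSE)), "genes collapsed )\n")
  cat("  excluded (pseudogene/mito):", length(object@excluded), "\n")
  cat("  loci:", length(object@loci), " flanks:", length(object@flanks), "\n")
  cat("  genome:", if (length(object@genome)) paste(length(object@genome),
      "sequence(s)") else "absent", "\n")
})

#' @rdname ReferenceSet
#' @export
setGeneric("contigs", function(x) standardGeneric("contigs"))
#' @describeIn ReferenceSet CCA-tailed contig sequences.
#' @export
setMethod("contigs", "ReferenceSet", function(x) x@contigs)

#' @rdname ReferenceSet
#' @export
setGeneric("contigMembers", function(x) standardGeneric("contigMembers"))
#' @describeIn ReferenceSet Gene membership of each contig.
#' @export
setMethod("contigMembers", "ReferenceSet", function(x) x@members)

#' @rdname ReferenceSet
#' @export
setGeneric("isoacceptorOf", function(x) standardGeneric("isoacceptorOf"))
#' @describeIn ReferenceSet Isoacceptor label of each contig.
#' @export
setMethod("isoacceptorOf", "ReferenceSet", function(x) x@isoacceptor)

#' @rdname ReferenceSet
#' @export
setGeneric("excludedContigs", function(x) standardGeneric("excludedContigs"))
#' @describeIn ReferenceSet Contigs excluded as pseudogene/mitochondrial.
#' @export
setMethod("excludedContigs", "ReferenceSet", function(x) x@excluded)

#' @rdname ReferenceSet
#' @export
setGeneric("flankRegions", function(x) standardGeneric("flankRegions"))
#' @describeIn ReferenceSet Genomic flank intervals for pre-tRNA filtering.
#' @export
setMethod("flankRegions", "ReferenceSet", function(x) x@flanks)

#' @rdname ReferenceSet
#' @export
setGeneric("geneLoci", function(x) standardGeneric("geneLoci"))
#' @describeIn ReferenceSet Genomic loci of the input genes.
#' @export
setMethod("geneLoci", "ReferenceSet", function(x) x@loci)

#' @rdname ReferenceSet
#' @export
setGeneric("refGenome", function(x) standardGeneric("refGenome"))
#' @describeIn ReferenceSet Unmasked genome (empty \code{DNAStringSet} if absent).
#' @export
setMethod("refGenome", "ReferenceSet", function(x) x@genome)

#' @rdname ReferenceSet
#' @export
setGeneric("maskedGenome", function(x) standardGeneric("maskedGenome"))
#' @describeIn ReferenceSet Masked genome (empty \code{DNAStringSet} if absent).
#' @export
setMethod("maskedGenome", "ReferenceSet", function(x) x@maskedGenome)


## ---- sequence utilities ----------------------------------------------------

.normalizeSeq <- function(x, what = "sequence") {
  nm <- names(x)
  x <- toupper(as.character(x))
  names(x) <- nm
  x <- gsub("U", "T", x, fixed = TRUE)
  bad <- grepl("[^ACGTN]", x)
  if (any(bad))
    stop(what, " contains characters outside {A,C,G,T/U,N}: ",
         paste(head(which(bad), 3L), collapse = ", "))
  x
}

#' Append a CCA tail to mature tRNA sequences
#'
#' Mature tRNAs carry a 3' CCA trinucleotide that is not genome-encoded; it is
#' appended to every reference contig so that reads ending at the mature 3'
#' end align.  Appending is unconditional by default because inputs are
#' intron-less gene bodies without tails; set \code{ifAbsent = TRUE} to skip
#' sequences that already end in CCA.
#'
#' U is normalised to T and the result is returned in DNA alphabet.
#'
#' @param x Character vector or \link[Biostrings]{DNAStringSet} of sequences
#'   over \{A,C,G,T/U,N\}.
#' @param ifAbsent Only append when the sequence does not already end in CCA.
#' @return Character vector of tailed sequences (same names as input).
#' @examples
#' appendCCA("GGGAAAUCC")  # "GGGAAATCCCCA"
#' @export
appendCCA <- function(x, ifAbsent = FALSE) {
  s <- .normalizeSeq(x)
  if (any(!nzchar(s))) stop("empty sequence")
  if (ifAbsent) {
    has <- substring(s, pmax(nchar(s) - 2L, 1L)) == "CCA"
    s[!has] <- paste0(s[!has], "CCA")
  } else {
    s <- paste0(s, "CCA")
  }
  names(s) <- names(x)
  s
}

.checkGenes <- function(genes) {
  req <- c("gene_id", "sequence", "isoacceptor", "source", "pseudogene")
  miss <- setdiff(req, names(genes))
  if (length(miss))
    stop("genes table lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(genes$gene_id))
    stop("duplicate gene_ids: ",
         paste(unique(genes$gene_id[duplicated(genes$gene_id)]), collapse = ", "))
  ok <- c("db", "chromosomal_prediction", "mito_prediction")
  if (!all(genes$source %in% ok))
    stop("gene source must be one of ", paste(ok, collapse = ", "))
  invisible(genes)
}

.geneLociGRanges <- function(genes) {
  if (!all(c("chrom", "start", "end") %in% names(genes)) ||
      all(is.na(genes$start)))
    return(GRanges())
  has <- !is.na(genes$start) & !is.na(genes$end) & !is.na(genes$chrom)
  g <- genes[has, , drop = FALSE]
  if (any(g$end <= g$start)) stop("locus end must exceed start")
  strand <- if ("strand" %in% names(g)) g$strand else "+"
  gr <- GRanges(g$chrom, IRanges(g$start + 1L, g$end), strand = strand)
  mcols(gr)$gene_id <- g$gene_id
  gr
}

#' Collapse genes with identical sequences into contigs
#'
#' Genes (and pseudogenes) whose CCA-tailed sequences are identical at 100\%
#' are collapsed into a single reference contig, since reads cannot be
#' attributed among exact copies.  The contig id is the lexicographically
#' smallest member gene id.  A contig is flagged excluded only when all of its
#' members are pseudogenes or mitochondrial predictions; a mixed group keeps
#' the contig, attributing its reads to the functional copy.
#'
#' @param genes data.frame with columns \code{gene_id}, \code{sequence}
#'   (already CCA-tailed), \code{isoacceptor}, \code{source} (one of
#'   \code{db}, \code{chromosomal_prediction}, \code{mito_prediction}),
#'   \code{pseudogene} (logical) and optional \code{chrom}, \code{start},
#'   \code{end}, \code{strand} (0-based half-open loci).
#' @return A \code{\link{ReferenceSet}} with contigs, members, isoacceptor
#'   labels, exclusion flags and any gene loci (no genome, no flanks).
#' @export
collapseIdentical <- function(genes) {
  .checkGenes(genes)
  seqs <- .normalizeSeq(genes$sequence)
  if (nrow(genes) == 0L) {
    return(new("ReferenceSet", contigs = DNAStringSet(), members = list(),
               isoacceptor = character(), excluded = character(),
               loci = GRanges(), flanks = GRanges(),
               genome = DNAStringSet(), maskedGenome = DNAStringSet()))
  }
  grp <- split(seq_len(nrow(genes)), seqs)
  contigId <- vapply(grp, function(i) min(genes$gene_id[i]), character(1))
  ord <- order(contigId)
  grp <- grp[ord]; contigId <- contigId[ord]
  contigSeq <- DNAStringSet(setNames(names(grp), contigId))
  members <- lapply(grp, function(i) sort(genes$gene_id[i]))
  names(members) <- contigId
  iso <- vapply(grp, function(i) {
    genes$isoacceptor[i][order(genes$gene_id[i])[1L]]
  }, character(1))
  names(iso) <- contigId
  nonfunctional <- genes$pseudogene | genes$source == "mito_prediction"
  excl <- contigId[vapply(grp, function(i) all(nonfunctional[i]), logical(1))]
  new("ReferenceSet", contigs = contigSeq, members = members,
      isoacceptor = iso, excluded = unname(excl),
      loci = .geneLociGRanges(genes), flanks = GRanges(),
      genome = DNAStringSet(), maskedGenome = DNAStringSet())
}

#' Mask intervals of a genome with N
#'
#' Replaces every base inside the given intervals with \code{N}, leaving
#' lengths unchanged.  Used to blank the tRNA gene loci out of the genome so
#' that mature-tRNA reads map only to the tRNA contigs.
#'
#' @param genome \link[Biostrings]{DNAStringSet} named by chromosome.
#' @param loci \link[GenomicRanges]{GRanges} of intervals to mask (1-based
#'   inclusive, as usual for GRanges).  Overlaps are allowed.
#' @return Masked \code{DNAStringSet} of identical lengths.
#' @export
maskGenome <- function(genome, loci) {
  if (length(loci) == 0L) return(genome)
  if (!all(as.character(seqnames(loci)) %in% names(genome)))
    stop("interval on chromosome absent from genome")
  red <- reduce(loci, ignore.strand = TRUE)
  out <- genome
  for (chr in unique(as.character(seqnames(red)))) {
    r <- red[as.character(seqnames(red)) == chr]
    len <- width(genome[names(genome) == chr])
    if (any(start(r) < 1L) || any(end(r) > len))
      stop("interval out of bounds on ", chr)
    ir <- IRanges(start(r), end(r))
    repl <- vapply(width(ir), function(w) strrep("N", w), character(1))
    out[[chr]] <- replaceAt(genome[[chr]], ir, repl)
  }
  out
}

#' Flank intervals around tRNA loci for pre-tRNA detection
#'
#' Pre-tRNAs retain genomic leader/trailer sequence, so reads from them map
#' into the regions flanking the gene.  For each locus a flank of
#' \code{flankLen} bases is taken on either side, shifted \code{upShift} bases
#' away from the gene on the 5' side and \code{downShift} bases on the 3'
#' side (strand-mirrored on the minus strand), then clipped at chromosome
#' bounds.  The shifts keep the flanks clear of ragged mature ends.
#'
#' @param loci \link[GenomicRanges]{GRanges} of gene loci.
#' @param flankLen Flank length in bases (default 50).
#' @param upShift,downShift Gap between the gene and its 5' / 3' flank
#'   (defaults 3 and 6).
#' @param seqlengths Optional named integer vector of chromosome lengths for
#'   clipping (taken from \code{loci} seqinfo when present there).
#' @return \code{GRanges} of flank intervals; \code{mcols()} carry
#'   \code{gene_id} (when present on \code{loci}) and \code{side}
#'   (\code{"up"}/\code{"down"}, in the transcript sense).
#' @export
extractFlanks <- function(loci, flankLen = 50L, upShift = 3L, downShift = 6L,
                          seqlengths = NULL) {
  if (flankLen <= 0L) stop("flankLen must be positive")
  if (length(loci) == 0L) return(GRanges())
  minus <- as.character(strand(loci)) == "-"
  s <- start(loci); e <- end(loci)
  upStart <- ifelse(minus, e + upShift + 1L, s - upShift - flankLen)
  upEnd   <- ifelse(minus, e + upShift + flankLen, s - upShift - 1L)
  dnStart <- ifelse(minus, s - downShift - flankLen, e + downShift + 1L)
  dnEnd   <- ifelse(minus, s - downShift - 1L, e + downShift + flankLen)
  chr <- rep(as.character(seqnames(loci)), 2L)
  st  <- c(upStart, dnStart); en <- c(upEnd, dnEnd)
  side <- rep(c("up", "down"), each = length(loci))
  gid <- if (!is.null(mcols(loci)$gene_id))
    rep(mcols(loci)$gene_id, 2L) else rep(NA_character_, 2L * length(loci))
  st <- pmax(st, 1L)
  if (!is.null(seqlengths))
    en <- pmin(en, seqlengths[chr])
  keep <- en >= st
  gr <- GRanges(chr[keep], IRanges(st[keep], en[keep]),
                strand = rep(as.character(strand(loci)), 2L)[keep])
  mcols(gr)$gene_id <- gid[keep]
  mcols(gr)$side <- side[keep]
  gr
}

#' Build the full mapping reference
#'
#' Composes the reference-construction steps: CCA tailing, 100\%-identity
#' collapsing, genome masking and flank extraction.  With no genome the
#' result carries contigs only (no flanks, no masked genome).
#'
#' @inheritParams collapseIdentical
#' @param genome Optional \link[Biostrings]{DNAStringSet} genome; gene loci
#'   (from the genes table) are masked in it and flanks derived around them.
#' @param flankLen,upShift,downShift Flank geometry, see
#'   \code{\link{extractFlanks}}.
#' @param ccaIfAbsent Append CCA only when missing (see \code{\link{appendCCA}}).
#' @return A \code{\link{ReferenceSet}}.
#' @examples
#' genes <- data.frame(gene_id = c("tA", "tB"),
#'                     sequence = c("GGGAAATCC", "GGGAAATCC"),
#'                     isoacceptor = "AlaAGC", source = "db",
#'                     pseudogene = FALSE)
#' ref <- buildReference(genes)
#' contigs(ref)
#' @export
buildReference <- function(genes, genome = NULL, flankLen = 50L, upShift = 3L,
                           downShift = 6L, ccaIfAbsent = FALSE) {
  if (nrow(genes) == 0L) stop("genes table is empty")
  genes$sequence <- appendCCA(genes$sequence, ifAbsent = ccaIfAbsent)
  ref <- collapseIdentical(genes)
  if (!is.null(genome) && length(genome)) {
    genome <- DNAStringSet(.normalizeSeq(as.character(genome),
                                         "genome sequence"))
    if (length(ref@loci) == 0L)
      stop("a genome was supplied but the genes table carries no loci")
    sl <- setNames(width(genome), names(genome))
    ref@genome <- genome
    ref@maskedGenome <- maskGenome(genome, ref@loci)
    ref@flanks <- extractFlanks(ref@loci, flankLen = flankLen,
                                upShift = upShift, downShift = downShift,
                                seqlengths = sl)
  }
  validObject(ref)
  ref
}

#' Write a ReferenceSet to disk
#'
#' Writes the contig FASTA, flank intervals as BED6 (0-based half-open), the
#' contig-to-gene membership TSV and, when present, the masked genome FASTA.
#' Re-running on identical inputs produces byte-identical files.
#'
#' @param ref A \code{\link{ReferenceSet}}.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of written paths.
#' @export
writeReference <- function(ref, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(fasta = file.path(dir, "reference.fa"),
             bed = file.path(dir, "flanks.bed"),
             members = file.path(dir, "members.tsv"))
  writeXStringSet(contigs(ref), paths[["fasta"]])
  fl <- flankRegions(ref)
  bed <- data.frame(chrom = as.character(seqnames(fl)),
                    start = start(fl) - 1L, end = end(fl),
                    name = paste0(mcols(fl)$gene_id, "_", mcols(fl)$side),
                    score = 0L, strand = as.character(strand(fl)))
  write.table(bed, paths[["bed"]], sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  mem <- data.frame(contig = rep(names(contigMembers(ref)),
                                 lengths(contigMembers(ref))),
                    gene_id = unlist(contigMembers(ref), use.names = FALSE))
  mem$isoacceptor <- isoacceptorOf(ref)[mem$contig]
  mem$excluded <- mem$contig %in% excludedContigs(ref)
  write.table(mem, paths[["members"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (length(maskedGenome(ref))) {
    paths[["masked_genome"]] <- file.path(dir, "genome_masked.fa")
    writeXStringSet(maskedGenome(ref), paths[["masked_genome"]])
  }
  invisible(paths)
}
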