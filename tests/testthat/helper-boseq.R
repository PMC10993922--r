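# Shared fixtures, all built in code.

toyGenes <- function(seqs, ids = sprintf("g%02d", seq_along(seqs)),
                     iso = "AlaAGC", source = "db", pseudogene = FALSE,
                     loci = NULL) {
  if (!length(seqs)) {
    iso <- character(0); source <- character(0); pseudogene <- logical(0)
  }
  g <- data.frame(gene_id = ids, sequence = seqs, isoacceptor = iso,
                  source = source, pseudogene = pseudogene,
                  stringsAsFactors = FALSE)
  if (!is.null(loci)) g <- cbind(g, loci)
  g
}

randomSeq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                      replace = TRUE), collapse = "")

# Reference with randomized contigs of a given body length; deterministic
# under the caller's seed.
randomRef <- function(nContigs = 5L, bodyLen = 60L, iso = NULL) {
  seqs <- replicate(nContigs, randomSeq(bodyLen))
  if (is.null(iso)) iso <- sprintf("Iso%02d", seq_len(nContigs))
  buildReference(toyGenes(seqs, iso = iso))
}

# Minimal SAM writer: records are lists with qname, flag, rname, pos (1-based),
# mapq, seq.
writeToySam <- function(path, contigs, records) {
  hdr <- c("@HD\tVN:1.6",
           sprintf("@SQ\tSN:%s\tLN:%d", names(contigs), nchar(contigs)))
  body <- vapply(records, function(r) {
    cigar <- if (bitwAnd(r$flag, 4L) > 0L) "*" else
      paste0(nchar(r$seq), "M")
    sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s",
            r$qname, r$flag, r$rname, r$pos, r$mapq, cigar, r$seq,
            strrep("I", nchar(r$seq)))
  }, character(1))
  writeLines(c(hdr, body), path)
  path
}

# Synthetic alignment table (the package's internal representation).
makeAln <- function(contig, start, mapq = 30L, len = 1L,
                    read_id = sprintf("r%05d", seq_along(start))) {
  if (!length(start))
    return(data.frame(read_id = character(), contig = character(),
                      start = integer(), end = integer(), mapq = integer(),
                      stringsAsFactors = FALSE))
  data.frame(read_id = read_id, contig = contig, start = as.integer(start),
             end = as.integer(start + len), mapq = as.integer(mapq),
             stringsAsFactors = FALSE)
}

# Expand per-position count vectors into an alignment table, one row per read.
alnFromCounts <- function(contig, counts) {
  pos <- rep(seq_along(counts) - 1L, counts)   # 0-based starts
  if (!length(pos)) return(makeAln(character(0), integer(0)))
  makeAln(rep(contig, length(pos)), pos,
          read_id = sprintf("%s_r%05d", contig, seq_along(pos)))
}
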