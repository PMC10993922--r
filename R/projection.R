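## Projection of per-gene positions onto isoacceptor canonical coordinates
## through multiple-alignment columns.  Profiles are consumed as Stockholm
## files (one per isoacceptor); rows cover the tRNA body only, so positions
## inside the appended CCA tail map to synthetic labels CCA1..CCA3.

.GAPCHARS <- c(".", "-", "~")

#' AlignmentProfile: a per-isoacceptor multiple alignment
#'
#' @slot isoacceptor Isoacceptor label.
#' @slot rows Named character vector of equal-length gapped sequences
#'   (gene id to row; CCA tails excluded).
#' @slot labels Character vector of per-column canonical position labels
#'   (NA for unlabelled/gap columns); length equals the alignment width, or
#'   zero when no reference annotation was available.
#' @export
setClass("AlignmentProfile",
  slots = c(isoacceptor = "character", rows = "character",
            labels = "character"))

setValidity("AlignmentProfile", function(object) {
  msg <- character()
  if (length(object@rows)) {
    w <- unique(nchar(object@rows))
    if (length(w) != 1L) msg <- c(msg, "all gapped rows must be equal length")
    else if (length(object@labels) && length(object@labels) != w)
      msg <- c(msg, "labels length must equal alignment width")
    if (is.null(names(object@rows)) || any(!nzchar(names(object@rows))))
      msg <- c(msg, "rows must be named by gene id")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "AlignmentProfile", function(object) {
  cat("AlignmentProfile", object@isoacceptor, ":", length(object@rows),
      "rows x", if (length(object@rows)) nchar(object@rows[[1L]]) else 0L,
      "columns;", sum(!is.na(object@labels)), "labelled columns\n")
})

#' @rdname AlignmentProfile
#' @param x An \code{AlignmentProfile}.
#' @export
setGeneric("profileRows", function(x) standardGeneric("profileRows"))
#' @describeIn AlignmentProfile Gapped rows.
#' @export
setMethod("profileRows", "AlignmentProfile", function(x) x@rows)

#' @rdname AlignmentProfile
#' @export
setGeneric("columnLabels", function(x) standardGeneric("columnLabels"))
#' @describeIn AlignmentProfile Canonical column labels (NA where absent).
#' @export
setMethod("columnLabels", "AlignmentProfile", function(x) x@labels)

#' Parse a Stockholm multiple alignment
#'
#' Reads one (possibly interleaved, multi-block) Stockholm file into an
#' \code{\link{AlignmentProfile}}.  A \code{#=GC RF} reference-annotation
#' line, when present, defines the canonical column labels: its non-gap
#' columns are numbered 1, 2, ... and those numbers become the labels (so a
#' consensus whose 46th non-gap column is the variable-loop G yields label
#' \code{"46"} there).
#'
#' @param path Stockholm file.
#' @param isoacceptor Isoacceptor label; defaults to the file name without
#'   extension.
#' @return An \code{\link{AlignmentProfile}}.
#' @export
parseStockholm <- function(path, isoacceptor = NULL) {
  if (is.null(isoacceptor))
    isoacceptor <- file_path_sans_ext(basename(path))
  lines <- readLines(path)
  if (!any(trimws(lines) == "//"))
    stop("not a valid Stockholm file (missing terminal '//'): ", path)
  rows <- list(); rf <- character(0)
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (trimws(ln) == "//") break
    if (!nzchar(trimws(ln)) || startsWith(ln, "# STOCKHOLM")) next
    if (startsWith(ln, "#=GC")) {
      f <- strsplit(trimws(ln), "\\s+")[[1]]
      if (length(f) >= 3L && f[2L] == "RF") rf <- c(rf, f[3L])
      next
    }
    if (startsWith(ln, "#")) next
    f <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(f) != 2L)
      stop("malformed Stockholm sequence line ", i, " in ", path)
    rows[[f[1L]]] <- c(rows[[f[1L]]], f[2L])
  }
  rows <- vapply(rows, paste, character(1), collapse = "")
  if (length(rows) && length(unique(nchar(rows))) != 1L) {
    bad <- names(rows)[nchar(rows) != nchar(rows[[1L]])][1L]
    stop("ragged alignment rows in ", path, " (e.g. '", bad, "', line ",
         which(grepl(paste0("^", bad, "\\s"), lines))[1L], ")")
  }
  labels <- character(0)
  if (length(rf)) {
    rf <- paste(rf, collapse = "")
    if (length(rows) && nchar(rf) != nchar(rows[[1L]]))
      stop("#=GC RF length disagrees with alignment width in ", path)
    ch <- strsplit(rf, "")[[1]]
    nongap <- !(ch %in% .GAPCHARS)
    labels <- rep(NA_character_, length(ch))
    labels[nongap] <- as.character(cumsum(nongap)[nongap])
  }
  new("AlignmentProfile", isoacceptor = isoacceptor, rows = rows,
      labels = labels)
}

#' Write an AlignmentProfile as Stockholm
#'
#' Counterpart of \code{\link{parseStockholm}}; used to generate toy
#' profiles programmatically.
#'
#' @param profile An \code{\link{AlignmentProfile}}.
#' @param path Output file.
#' @return Invisibly, \code{path}.
#' @export
writeStockholm <- function(profile, path) {
  rows <- profileRows(profile)
  lines <- c("# STOCKHOLM 1.0",
             sprintf("%-20s %s", names(rows), unname(rows)))
  lab <- columnLabels(profile)
  if (length(lab)) {
    rf <- ifelse(is.na(lab), ".", "x")
    lines <- c(lines, sprintf("%-20s %s", "#=GC RF",
                              paste(rf, collapse = "")))
  }
  writeLines(c(lines, "//"), path)
  invisible(path)
}

#' Map an ungapped gene position to its alignment column
#'
#' Returns the alignment column holding the \code{position}-th non-gap
#' character of the gene's row, plus that column's canonical label when the
#' profile carries labels.  Positions up to three bases past the aligned
#' body (the appended CCA tail, which alignments exclude) map to synthetic
#' labels \code{"CCA1"}..\code{"CCA3"} with \code{NA} column.
#'
#' @param profile An \code{\link{AlignmentProfile}}.
#' @param geneId Row name.
#' @param position 1-based ungapped position.
#' @return List with \code{column} (integer or NA) and \code{label}
#'   (character or NA).
#' @export
mapPosition <- function(profile, geneId, position) {
  rows <- profileRows(profile)
  if (!geneId %in% names(rows)) stop("gene not in profile: ", geneId)
  ch <- strsplit(rows[[geneId]], "")[[1]]
  nongap <- which(!(ch %in% .GAPCHARS))
  if (position < 1L) stop("position must be >= 1")
  if (position > length(nongap)) {
    off <- position - length(nongap)
    if (off <= 3L)
      return(list(column = NA_integer_, label = paste0("CCA", off)))
    stop("position ", position, " beyond aligned body + CCA of ", geneId)
  }
  col <- nongap[position]
  lab <- columnLabels(profile)
  list(column = col,
       label = if (length(lab)) lab[col] else as.character(col))
}

#' Invert a column back to the ungapped position
#'
#' Inverse of \code{\link{mapPosition}} on non-gap columns of a row.
#'
#' @inheritParams mapPosition
#' @param column Alignment column index.
#' @return 1-based ungapped position, or NA when the row has a gap there.
#' @export
columnToPosition <- function(profile, geneId, column) {
  rows <- profileRows(profile)
  if (!geneId %in% names(rows)) stop("gene not in profile: ", geneId)
  ch <- strsplit(rows[[geneId]], "")[[1]]
  if (column < 1L || column > length(ch)) stop("column out of range")
  if (ch[column] %in% .GAPCHARS) return(NA_integer_)
  sum(!(ch[seq_len(column)] %in% .GAPCHARS))
}

## Find the profile row matching a contig: exact equality between the
## ungapped row and the contig body (contig minus its CCA tail).
.matchProfileRow <- function(contigSeq, profiles) {
  body <- substring(contigSeq, 1L, nchar(contigSeq) - 3L)
  for (p in profiles) {
    rows <- profileRows(p)
    ung <- toupper(gsub("[.~-]", "", rows))
    ung <- gsub("U", "T", ung, fixed = TRUE)
    hit <- which(ung == body)
    if (length(hit))
      return(list(profile = p, geneId = names(rows)[hit[1L]]))
  }
  NULL
}

#' Trivial profiles from equal-length reference contigs
#'
#' Groups contigs by isoacceptor into gap-free profiles (one row per contig
#' body).  Only valid when all bodies within an isoacceptor have equal
#' length, as simulated references do; real data should use curated
#' Stockholm alignments instead.
#'
#' @param ref A \code{\link{ReferenceSet}}.
#' @return Named list of \code{\link{AlignmentProfile}}s, one per
#'   isoacceptor.
#' @export
ungappedProfiles <- function(ref) {
  cs <- as.character(contigs(ref))
  body <- substring(cs, 1L, nchar(cs) - 3L)
  iso <- isoacceptorOf(ref)
  out <- list()
  for (lab in sort(unique(iso))) {
    rows <- body[names(iso)[iso == lab]]
    if (length(unique(nchar(rows))) != 1L)
      stop("isoacceptor ", lab, " has bodies of unequal length; supply a ",
           "Stockholm alignment instead")
    w <- nchar(rows[[1L]])
    out[[lab]] <- new("AlignmentProfile", isoacceptor = lab, rows = rows,
                      labels = as.character(seq_len(w)))
  }
  out
}

#' Aggregate candidate sites at the isoacceptor level
#'
#' Projects each candidate's guanosine position through its isoacceptor
#' alignment and merges candidates from member genes that land on the same
#' column into one isoacceptor-level site (maximum score; member contigs
#' retained).  Profile rows are matched to contigs by exact
#' ungapped-sequence equality (CCA excluded); candidates whose contig
#' matches no profile are passed through unprojected with
#' \code{projected = FALSE} and a warning.
#'
#' @param candidates Candidate table from \code{\link{callCandidates}}.
#' @param profiles List of \code{\link{AlignmentProfile}}s.
#' @param ref The \code{\link{ReferenceSet}} the candidates were called on.
#' @return data.frame keyed by (isoacceptor, column/label): isoacceptor,
#'   column, label, score (max over members), n_members, members
#'   (comma-separated contig ids), projected.
#' @export
aggregateIsoacceptor <- function(candidates, profiles, ref) {
  cs <- as.character(contigs(ref))
  empty <- data.frame(isoacceptor = character(), column = integer(),
                      label = character(), score = numeric(),
                      n_members = integer(), members = character(),
                      projected = logical(), stringsAsFactors = FALSE)
  if (nrow(candidates) == 0L) return(empty)
  rows <- lapply(seq_len(nrow(candidates)), function(i) {
    cand <- candidates[i, ]
    m <- .matchProfileRow(cs[[cand$contig]], profiles)
    if (is.null(m)) {
      warning("contig ", cand$contig, " matches no profile row; ",
              "candidate passed through unprojected")
      return(data.frame(isoacceptor = cand$isoacceptor, column = NA_integer_,
                        label = as.character(cand$g_position),
                        score = cand$score, n_members = 1L,
                        members = cand$contig, projected = FALSE,
                        stringsAsFactors = FALSE))
    }
    mp <- mapPosition(m$profile, m$geneId, cand$g_position)
    data.frame(isoacceptor = m$profile@isoacceptor,
               column = if (is.na(mp$column)) NA_integer_ else mp$column,
               label = mp$label, score = cand$score, n_members = 1L,
               members = cand$contig, projected = TRUE,
               stringsAsFactors = FALSE)
  })
  tbl <- do.call(rbind, rows)
  key <- paste(tbl$isoacceptor, tbl$column, tbl$label, tbl$projected)
  merged <- lapply(split(tbl, key), function(g) {
    if (!g$projected[1L]) return(g)
    data.frame(isoacceptor = g$isoacceptor[1L], column = g$column[1L],
               label = g$label[1L], score = max(g$score),
               n_members = nrow(g),
               members = paste(sort(g$members), collapse = ","),
               projected = TRUE, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, merged)
  res <- res[order(res$isoacceptor, res$column), , drop = FALSE]
  rownames(res) <- NULL
  res
}
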