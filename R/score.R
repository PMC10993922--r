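## The cleavage-score statistic and candidate m7G calling.
##
## cleavage ratio  r = (n + alpha) / N   (start count over aligned total)
## cleavage score  s = log2(r_treated / r_untreated)
##
## A symmetric pseudocount alpha (default 0.5) keeps scores finite and
## antisymmetric under condition swap; alpha = 0 reproduces the literal
## ratio and errors on zero counts.  Candidates are restricted to
## guanosines within the N..N+3 stop window upstream of the score peak.

#' Cleavage ratio
#'
#' Fraction of a contig's aligned reads whose fragment start site is a given
#' position, with a pseudocount: \code{(n + alpha) / N}.
#'
#' @param n Start-site count(s).
#' @param N Total aligned reads on the contig (must be >= 1).
#' @param alpha Pseudocount (default 0.5).
#' @return Numeric ratio(s).
#' @examples
#' cleavageRatio(640, 1000, alpha = 0)   # 0.64
#' @export
cleavageRatio <- function(n, N, alpha = 0.5) {
  if (any(N < 1)) stop("cleavage ratio undefined for N < 1")
  if (any(n < 0) || alpha < 0) stop("counts and alpha must be non-negative")
  (n + alpha) / N
}

#' Cleavage score
#'
#' \code{log2(rTreated / rUntreated)}: the calling statistic.  Antisymmetric
#' under swapping the two conditions.
#'
#' @param rTreated,rUntreated Cleavage ratios (must be positive).
#' @return Numeric score(s).
#' @examples
#' cleavageScore(0.64, 0.005)   # 7
#' @export
cleavageScore <- function(rTreated, rUntreated) {
  if (any(rTreated <= 0) || any(rUntreated <= 0))
    stop("cleavage ratios must be positive (use a pseudocount upstream)")
  # difference of logs, so swapping the conditions negates the score exactly
  log2(rTreated) - log2(rUntreated)
}

#' Per-position cleavage-score table
#'
#' Builds one row per position of every contig shared by the two count
#' tables, with counts, totals, pseudocounted ratios, the log2 cleavage
#' score and the reference base.  Contigs lacking aligned reads in either
#' condition are skipped with a message.  Counts are taken post support
#' thresholding (unsupported cells are zero), while totals always cover all
#' aligned reads.
#'
#' @param treated,untreated \code{\link{StartCountTable}}s of the two
#'   conditions (their condition labels must differ).
#' @param ref A \code{\link{ReferenceSet}}.
#' @param alpha Pseudocount added to both conditions' counts (default 0.5).
#' @return data.frame with columns contig, isoacceptor, position (1-based),
#'   ref_base, n_treated, N_treated, n_untreated, N_untreated,
#'   ratio_treated, ratio_untreated, score; attribute \code{alpha}.
#' @export
scoreTable <- function(treated, untreated, ref, alpha = 0.5) {
  stopifnot(is(treated, "StartCountTable"), is(untreated, "StartCountTable"))
  if (identical(conditionOf(treated), conditionOf(untreated)))
    stop("the two count tables carry the same condition label")
  if (alpha < 0) stop("alpha must be non-negative")
  cs <- contigs(ref)
  shared <- intersect(intersect(names(libTotals(treated)),
                                names(libTotals(untreated))), names(cs))
  usable <- shared[libTotals(treated)[shared] >= 1 &
                   libTotals(untreated)[shared] >= 1]
  skipped <- setdiff(union(names(libTotals(treated)),
                           names(libTotals(untreated))), usable)
  if (length(skipped))
    message("skipping ", length(skipped),
            " contig(s) without reads in both conditions: ",
            paste(head(skipped, 5L), collapse = ", "))
  usable <- sort(usable)
  ctT <- startCounts(treated); ctU <- startCounts(untreated)
  rows <- lapply(usable, function(ctg) {
    L <- width(cs)[names(cs) == ctg]
    nT <- integer(L); nU <- integer(L)
    t1 <- ctT[ctT$contig == ctg, ]; u1 <- ctU[ctU$contig == ctg, ]
    nT[t1$pos] <- t1$count; nU[u1$pos] <- u1$count
    data.frame(contig = ctg,
               isoacceptor = unname(isoacceptorOf(ref)[ctg]),
               position = seq_len(L),
               ref_base = strsplit(as.character(cs[[ctg]]), "")[[1]],
               n_treated = nT,
               N_treated = unname(libTotals(treated)[ctg]),
               n_untreated = nU,
               N_untreated = unname(libTotals(untreated)[ctg]),
               stringsAsFactors = FALSE)
  })
  tbl <- do.call(rbind, rows)
  if (is.null(tbl)) stop("no contig usable in both conditions")
  if (alpha == 0 && (any(tbl$n_treated == 0) || any(tbl$n_untreated == 0)))
    stop("alpha = 0 with zero counts: scores undefined; use alpha > 0")
  tbl$ratio_treated <- cleavageRatio(tbl$n_treated, tbl$N_treated, alpha)
  tbl$ratio_untreated <- cleavageRatio(tbl$n_untreated, tbl$N_untreated, alpha)
  tbl$score <- cleavageScore(tbl$ratio_treated, tbl$ratio_untreated)
  attr(tbl, "alpha") <- alpha
  rownames(tbl) <- NULL
  tbl
}

#' Call candidate m7G sites from a cleavage-score table
#'
#' A position qualifies when its score exceeds \code{threshold} and its
#' treated start count is positive (guarding against pseudocount-only
#' artifacts).  Qualifying positions on a contig are grouped into windows
#' whose consecutive members are at most \code{maxGap} apart, reflecting the
#' N..N+3 reverse-transcription stop spread.  For each window the peak is
#' the maximum-score position (ties break to the smaller coordinate), and
#' the candidate guanosine is the largest position \code{g <= peak} with
#' reference base G and \code{peak - g <= 3}.  Windows with no such G are
#' discarded: cleavage at abasic sites of other modifications (m3C,
#' dihydrouridine) arises from non-G parent bases, and restricting calls to
#' guanosines removes those off-targets.
#'
#' @param tbl Score table from \code{\link{scoreTable}}.
#' @param threshold Score threshold \eqn{\tau}; positions with
#'   \code{score > threshold} qualify.  Default 6.5 (the conservative
#'   preset); 5 is the documented operating point for broader candidate
#'   lists.
#' @param maxGap Maximum gap between qualifying positions in one window
#'   (default 3).
#' @return data.frame of candidate sites: contig, isoacceptor, g_position,
#'   peak_position, score, window_start, window_end, n_treated (at the
#'   peak), sorted by (contig, g_position).
#' @export
callCandidates <- function(tbl, threshold = 6.5, maxGap = 3L) {
  out <- list()
  for (ctg in unique(tbl$contig)) {
    t1 <- tbl[tbl$contig == ctg, ]
    t1 <- t1[order(t1$position), ]
    qual <- t1[t1$score > threshold & t1$n_treated > 0, ]
    if (nrow(qual) == 0L) next
    grp <- cumsum(c(1L, diff(qual$position) > maxGap))
    for (g in split(qual, grp)) {
      peakIdx <- which(g$score == max(g$score))[1L]
      peak <- g$position[peakIdx]
      cand <- t1$position[t1$ref_base == "G" & t1$position <= peak &
                            peak - t1$position <= 3L]
      if (length(cand) == 0L) next
      gpos <- max(cand)
      out[[length(out) + 1L]] <- data.frame(
        contig = ctg, isoacceptor = g$isoacceptor[1L],
        g_position = gpos, peak_position = peak,
        score = g$score[peakIdx],
        window_start = min(g$position), window_end = max(g$position),
        n_treated = g$n_treated[peakIdx], stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(contig = character(), isoacceptor = character(),
               g_position = integer(), peak_position = integer(),
               score = numeric(), window_start = integer(),
               window_end = integer(), n_treated = integer(),
               stringsAsFactors = FALSE)
  res <- res[order(res$contig, res$g_position), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Compare candidate call sets between two analyses
#'
#' Set comparison of calls (e.g. wild type versus methyltransferase
#' knock-out), keyed per isoacceptor and position (falling back to the
#' contig when an isoacceptor label is missing).
#'
#' @param callsA,callsB Candidate tables from \code{\link{callCandidates}}.
#' @param labels Length-2 character naming the two sets in the output.
#' @return data.frame with key columns (isoacceptor, g_position) and
#'   \code{status} in \{both, a_only, b_only\}; per-status counts are in
#'   \code{attr(, "counts")}.
#' @export
compareConditions <- function(callsA, callsB, labels = c("a", "b")) {
  keyOf <- function(d) {
    iso <- d$isoacceptor
    iso[is.na(iso)] <- d$contig[is.na(iso)]
    paste(iso, d$g_position, sep = ":")
  }
  ka <- unique(keyOf(callsA)); kb <- unique(keyOf(callsB))
  keys <- sort(union(ka, kb))
  status <- ifelse(keys %in% ka & keys %in% kb, "both",
                   ifelse(keys %in% ka, paste0(labels[1L], "_only"),
                          paste0(labels[2L], "_only")))
  parts <- strsplit(keys, ":", fixed = TRUE)
  res <- data.frame(
    isoacceptor = vapply(parts, `[`, character(1), 1L),
    g_position = as.integer(vapply(parts, `[`, character(1), 2L)),
    status = status, stringsAsFactors = FALSE)
  attr(res, "counts") <- table(factor(status, levels = c(
    "both", paste0(labels[1L], "_only"), paste0(labels[2L], "_only"))))
  res
}
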