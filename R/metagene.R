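#' Extract an anchor-by-position matrix from a signal track
#'
#' Builds one row per anchor covering relative positions \code{-L..+R} in
#' transcription direction: for a plus-strand anchor at p the row reads
#' forward-strand values at p-L..p+R; for a minus-strand anchor it reads
#' reverse-strand values at p+L..p-R (descending), so column order always
#' follows transcription. By default the strand-matched track vector is
#' used, which for a score track means the non-template strand of the
#' anchoring transcript. Anchors whose window extends past a chromosome end
#' are dropped with a warning; \code{NA} track values (e.g. the unscored
#' half-window at chromosome ends) propagate and are excluded from means
#' downstream.
#'
#' @param track A \code{\link{signal_track}}.
#' @param anchors A stranded \code{GRanges} of width-1 anchor positions.
#' @param L,R Bases to include upstream/downstream of the anchor.
#' @param strand_select \code{"same"} (default) uses the anchor-strand
#'   vector; \code{"opposite"}, \code{"fwd"} or \code{"rev"} override.
#' @return Numeric matrix with \code{length(anchors)} rows (minus dropped)
#'   and \code{L + R + 1} columns named by relative position.
#' @export
extract_matrix <- function(track, anchors, L = 500L, R = 500L,
                           strand_select = c("same", "opposite", "fwd", "rev")) {
  strand_select <- match.arg(strand_select)
  if (length(anchors) == 0L) stop("empty anchor list")
  if (any(width(anchors) != 1L)) stop("anchors must have width 1")
  pos <- start(anchors)
  chrom <- as.character(seqnames(anchors))
  astr <- as.character(strand(anchors))
  if (any(astr == "*")) stop("anchors must be stranded")
  n <- track$seqlengths[chrom]
  ok <- ifelse(astr == "+", pos - L >= 1L & pos + R <= n,
               pos + L <= n & pos - R >= 1L)
  if (any(!ok)) warning(sum(!ok), " anchor(s) dropped: window exceeds chromosome")
  if (!any(ok)) stop("no usable anchors")
  idx <- which(ok)
  mat <- matrix(NA_real_, length(idx), L + R + 1L,
                dimnames = list(NULL, as.character(seq(-L, R))))
  for (j in seq_along(idx)) {
    i <- idx[j]
    use <- switch(strand_select,
                  same = astr[i],
                  opposite = if (astr[i] == "+") "-" else "+",
                  fwd = "+", rev = "-")
    v <- track_vector(track, chrom[i], use)
    mat[j, ] <- if (astr[i] == "+") v[(pos[i] - L):(pos[i] + R)]
                else v[(pos[i] + L):(pos[i] - R)]
  }
  mat
}

#' Bin an anchor matrix into a metagene profile
#'
#' Averages the matrix column-wise after grouping columns into consecutive
#' bins of \code{bin_width} positions (5-bp windows by default, mirroring
#' 5-bp sliding-window profiling). The bin mean is the mean over all
#' non-missing cells in the bin; \code{n} is the largest per-column count of
#' contributing anchors within the bin.
#'
#' @param mat Matrix from \code{\link{extract_matrix}}.
#' @param bin_width Columns per bin (default 5).
#' @return Data frame with \code{bin_center} (mean relative position),
#'   \code{mean}, \code{n}.
#' @export
metagene_profile <- function(mat, bin_width = 5L) {
  if (!nrow(mat)) stop("empty matrix")
  rel <- as.integer(colnames(mat))
  bin <- (seq_along(rel) - 1L) %/% bin_width
  centers <- tapply(rel, bin, mean)
  means <- tapply(seq_along(rel), bin, function(cols)
    mean(mat[, cols, drop = FALSE], na.rm = TRUE))
  ns <- tapply(seq_along(rel), bin, function(cols)
    max(colSums(!is.na(mat[, cols, drop = FALSE]))))
  data.frame(bin_center = as.numeric(centers), mean = as.numeric(means),
             n = as.integer(ns))
}

#' Welch comparison of upstream vs downstream flanks
#'
#' For each anchor, averages the track over the 50-bp (by default) flank
#' upstream (relative positions -flank..-1) and downstream (+1..+flank) of
#' the anchor in transcription direction; the anchor base itself belongs to
#' neither flank. A two-sided Welch two-sample t test compares the
#' per-anchor upstream and downstream means. Anchors with any missing value
#' in either flank are dropped.
#'
#' @param track A \code{\link{signal_track}}.
#' @param anchors A stranded width-1 \code{GRanges} (e.g. TES positions).
#' @param flank Flank width in bases (default 50).
#' @param pooled Pool per-base values instead of per-anchor means (the
#'   per-anchor unit is the default; pooling treats every base as an
#'   observation).
#' @param strand_select Passed to \code{\link{extract_matrix}}.
#' @return List of class \code{flank_comparison}: \code{upstream},
#'   \code{downstream} (per-anchor means), \code{upstream_mean},
#'   \code{downstream_mean}, \code{t_statistic}, \code{p_value}, \code{n}.
#' @export
flank_test <- function(track, anchors, flank = 50L, pooled = FALSE,
                       strand_select = "same") {
  mat <- extract_matrix(track, anchors, L = flank, R = flank,
                        strand_select = strand_select)
  up_cols <- 1:flank
  down_cols <- (flank + 2L):(2L * flank + 1L)
  complete <- !apply(is.na(mat[, c(up_cols, down_cols), drop = FALSE]), 1, any)
  if (sum(complete) < 2L) stop("fewer than 2 anchors with complete flanks")
  mat <- mat[complete, , drop = FALSE]
  if (pooled) {
    up <- as.numeric(mat[, up_cols])
    down <- as.numeric(mat[, down_cols])
  } else {
    up <- rowMeans(mat[, up_cols, drop = FALSE])
    down <- rowMeans(mat[, down_cols, drop = FALSE])
  }
  tt <- tryCatch(t.test(down, up, var.equal = FALSE),
                 error = function(e) NULL)
  if (is.null(tt)) {
    # degenerate: both sides essentially constant
    equal <- isTRUE(all.equal(mean(down), mean(up)))
    tt <- list(statistic = c(t = if (equal) 0 else sign(mean(down) - mean(up)) * Inf),
               p.value = if (equal) 1 else 0)
  }
  structure(list(upstream = up, downstream = down,
                 upstream_mean = mean(up), downstream_mean = mean(down),
                 t_statistic = unname(tt$statistic), p_value = tt$p.value,
                 n = nrow(mat), flank = flank,
                 test = "Welch two-sample t test, two-sided"),
            class = "flank_comparison")
}

#' @export
print.flank_comparison <- function(x, ...) {
  cat(sprintf(paste0("Welch two-sample t test (%d-bp flanks, n = %d anchors)\n",
                     "  upstream mean   = %.4f\n  downstream mean = %.4f\n",
                     "  t = %.4f, p = %.4g\n"),
              x$flank, x$n, x$upstream_mean, x$downstream_mean,
              x$t_statistic, x$p_value))
  invisible(x)
}

#' Normalized position of the maximum signal along each transcript
#'
#' For each transcript, finds the position of the maximum strand-matched
#' per-base signal within the transcript and reports it as a fraction of
#' transcript length in (0, 1], measured in transcription direction (1 = at
#' the TES). Ties resolve to the most 3' position — a conservative choice
#' that is flagged because uniform signal then maps to 1. Transcripts whose
#' signal is entirely zero or missing are skipped and counted.
#'
#' @param track A \code{\link{signal_track}}.
#' @param transcripts A stranded \code{GRanges}.
#' @return Numeric vector of normalized positions; the number of skipped
#'   transcripts is attached as attribute \code{"skipped"}.
#' @export
max_signal_positions <- function(track, transcripts) {
  res <- rep(NA_real_, length(transcripts))
  ties <- 0L
  for (i in seq_along(transcripts)) {
    chrom <- as.character(seqnames(transcripts))[i]
    s <- as.character(strand(transcripts))[i]
    v <- track_vector(track, chrom, s)[start(transcripts)[i]:end(transcripts)[i]]
    if (s == "-") v <- rev(v)   # transcription direction
    if (all(is.na(v)) || max(v, na.rm = TRUE) <= 0) next
    hits <- which(v == max(v, na.rm = TRUE))
    if (length(hits) > 1L) ties <- ties + 1L
    res[i] <- max(hits) / length(v)
  }
  skipped <- sum(is.na(res))
  if (skipped > 0L)
    message(skipped, " transcript(s) with no positive signal skipped")
  if (ties > 0L)
    message(ties, " transcript(s) had tied maxima resolved to the 3'-most position")
  structure(res[!is.na(res)], skipped = skipped)
}
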