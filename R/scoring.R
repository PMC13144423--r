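#' Configuration for the windowed richness score
#'
#' The statistic scores a window of width \code{2 * half_width + 1} centered
#' on each genomic position: the number of matching bases, plus a bonus for
#' every run of consecutive matches (a run of length x contributes
#' x(x-1)/2, i.e. 1 + 2 + ... + (x-1)), minus the length of the longest run
#' of consecutive non-matching bases, clamped at zero. With the defaults
#' (\code{match = "T"}, \code{half_width = 3}) this is the T-score over the
#' 7-bp window k-3..k+3; \code{match = c("A","T")} gives the AT-score.
#'
#' @param match Character vector of matching bases, a nonempty proper subset
#'   of \{A,C,G,T\}.
#' @param half_width Integer half-window (default 3, i.e. 7-bp windows).
#' @return An object of class \code{scoring_config}.
#' @export
scoring_config <- function(match = "T", half_width = 3L) {
  match <- toupper(match)
  if (!length(match) || !all(match %in% c("A", "C", "G", "T")) ||
      length(unique(match)) >= 4L)
    stop("match must be a nonempty proper subset of {A,C,G,T}")
  half_width <- as.integer(half_width)
  if (half_width < 1L) stop("half_width must be >= 1")
  structure(list(match = sort(unique(match)), half_width = half_width),
            class = "scoring_config")
}

complement_config <- function(config) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  scoring_config(unname(comp[config$match]), config$half_width)
}

#' Score a single window (direct-formula reference)
#'
#' Computes the richness score of one window directly from its run
#' decomposition: \code{max(t + sum_i x_i (x_i - 1) / 2 - g, 0)}, where t is
#' the number of matching bases, x_i the lengths of the runs of consecutive
#' matches, and g the longest run of consecutive non-matches. N never
#' matches (it contributes to non-match runs). This is the reference
#' implementation; \code{\link{score_strand}} is the vectorized production
#' path and the two agree on every window (they are cross-checked
#' exhaustively in the test suite).
#'
#' @param window A single string of length \code{2 * half_width + 1} over
#'   \{A,C,G,T,N\}.
#' @param config A \code{\link{scoring_config}}.
#' @return List with \code{score} (integer) and \code{components} (list with
#'   \code{t}, \code{c}, \code{run_lengths}, \code{g}).
#' @examples
#' score_window("TTTTTTT", scoring_config("T"))$score   # 28
#' score_window("TTCCTTT", scoring_config("T"))$score   # 7
#' score_window("ATATATA", scoring_config(c("A","T")))$score  # 28
#' @export
score_window <- function(window, config = scoring_config()) {
  w <- 2L * config$half_width + 1L
  bases <- strsplit(toupper(window), "")[[1]]
  if (length(bases) != w)
    stop("window must have length ", w, ", got ", length(bases))
  if (!all(bases %in% c("A", "C", "G", "T", "N")))
    stop("window contains characters outside {A,C,G,T,N}")
  m <- bases %in% config$match
  r <- rle(m)
  run_lengths <- r$lengths[r$values]
  t <- sum(run_lengths)
  g <- if (any(!r$values)) max(r$lengths[!r$values]) else 0L
  bonus <- sum(run_lengths * (run_lengths - 1L) / 2L)
  score <- max(t + bonus - g, 0L)
  list(score = as.integer(score),
       components = list(t = as.integer(t), c = length(run_lengths),
                         run_lengths = as.integer(run_lengths),
                         g = as.integer(g)))
}

# Rolling sum of x over windows of `width`; length(out) = length(x) - width + 1.
roll_sum <- function(x, width) {
  cs <- c(0, cumsum(x))
  cs[(width + 1L):length(cs)] - cs[1:(length(cs) - width)]
}

# all_run(x, L)[p] is TRUE iff x[p..p+L-1] are all TRUE.
all_run <- function(x, L) {
  r <- x
  if (L >= 2L) for (j in 2:L) r <- r[1:(length(r) - 1L)] & x[j:length(x)]
  r
}

# Vectorized scorer for one match vector m over a chromosome.
# Returns a full-length vector with NA at positions within half_width of an
# end (the formula is defined on full windows only; truncated windows would
# change the score's range).
score_match_vector <- function(m, half_width) {
  n <- length(m)
  w <- 2L * half_width + 1L
  out <- rep(NA_real_, n)
  if (n < w) return(out)
  # t: matches per window
  t <- roll_sum(m, w)
  # bonus: each all-match sub-window of length d+1 fully inside the window
  # contributes 1 (a run of length x yields x(x-1)/2 such sub-windows).
  # The all-run indicator is extended incrementally across depths.
  bonus <- 0
  a <- m
  for (d in 1:(w - 1L)) {
    a <- a[-length(a)] & m[(d + 1L):n]    # all_run(m, d + 1), length n - d
    bonus <- bonus + roll_sum(a, w - d)   # sub-windows inside each window
  }
  # g: largest d such that some all-non-match sub-window of length d fits.
  nm <- !m
  g <- rep(0, n - w + 1L)
  b <- nm
  for (d in 1:w) {
    if (d > 1L) b <- b[-length(b)] & nm[d:n]  # all_run(nm, d)
    present <- roll_sum(b, w - d + 1L) > 0
    g[present] <- d
  }
  out[(half_width + 1L):(n - half_width)] <- pmax(t + bonus - g, 0)
  out
}

#' Score one strand of one chromosome
#'
#' Applies the windowed richness score at every position of a chromosome.
#' For the forward strand the window is read on the forward sequence; for
#' the reverse strand the score is that of the reverse-complemented window,
#' computed equivalently by matching the complemented base set on the
#' forward sequence (the score is invariant to reversing the window).
#' Positions are reported in forward-genome coordinates; positions within
#' \code{half_width} of a chromosome end are \code{NA}.
#'
#' @param genome A \code{DNAStringSet}.
#' @param chrom Chromosome name.
#' @param strand \code{"+"}/\code{"fwd"} or \code{"-"}/\code{"rev"}.
#' @param config A \code{\link{scoring_config}}.
#' @return Numeric vector of per-base scores (length = chromosome length).
#' @export
score_strand <- function(genome, chrom, strand = "+", config = scoring_config()) {
  if (!chrom %in% names(genome)) stop("chromosome not in genome: ", chrom)
  seq <- as.character(genome[[chrom]])
  w <- 2L * config$half_width + 1L
  if (nchar(seq) < w)
    stop("chromosome ", chrom, " is shorter than the scoring window (", w, " bp)")
  cfg <- if (strand %in% c("-", "rev", "reverse")) complement_config(config) else config
  bases <- strsplit(seq, "")[[1]]
  m <- bases %in% cfg$match
  score_match_vector(m, config$half_width)
}

#' Score a whole genome on both strands
#'
#' @param genome A \code{DNAStringSet}.
#' @param config A \code{\link{scoring_config}} (default: T-score).
#' @param verbose Log per-chromosome summary statistics to stderr.
#' @return A \code{\link{signal_track}} with forward- and reverse-strand
#'   scores for every chromosome.
#' @export
score_genome <- function(genome, config = scoring_config(), verbose = FALSE) {
  chroms <- names(genome)
  fwd <- lapply(chroms, function(ch) score_strand(genome, ch, "+", config))
  rev <- lapply(chroms, function(ch) score_strand(genome, ch, "-", config))
  names(fwd) <- names(rev) <- chroms
  if (verbose) {
    for (ch in chroms) {
      message(sprintf("score_genome: %s length=%d fwd mean=%.3f rev mean=%.3f",
                      ch, length(fwd[[ch]]),
                      mean(fwd[[ch]], na.rm = TRUE),
                      mean(rev[[ch]], na.rm = TRUE)))
    }
  }
  signal_track(fwd, rev)
}
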