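#' Find maximal homopolymer runs in a sequence
#'
#' Reports every maximal run of a single base A/C/G/T with length at least
#' \code{min_length}, in ascending start order. N never forms runs and
#' breaks runs of other bases.
#'
#' @param seq A single string over \{A,C,G,T,N\}.
#' @param min_length Minimum run length to report (default 3, i.e. runs
#'   longer than 2-mers).
#' @return Data frame with columns \code{base}, \code{start} (1-based
#'   position within \code{seq}), \code{length}.
#' @export
find_runs <- function(seq, min_length = 3L) {
  bases <- strsplit(toupper(seq), "")[[1]]
  if (length(bases) == 0L)
    return(data.frame(base = character(), start = integer(), length = integer()))
  r <- rle(bases)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values %in% c("A", "C", "G", "T") & r$lengths >= min_length
  data.frame(base = r$values[keep], start = starts[keep],
             length = r$lengths[keep], stringsAsFactors = FALSE)
}

#' Count non-overlapping homopolymer motifs
#'
#' Greedy left-to-right count of disjoint occurrences of the length-\code{len}
#' homopolymer of \code{base}; equivalently the sum over maximal runs of
#' \code{floor(run_length / len)}.
#'
#' @param seq A single string over \{A,C,G,T,N\}.
#' @param base The repeated base.
#' @param len Motif length (>= 2).
#' @param mode \code{"greedy"} (default) counts disjoint len-mers;
#'   \code{"exact"} counts maximal runs of exactly length \code{len}.
#' @return Integer count.
#' @export
count_nonoverlapping <- function(seq, base, len, mode = c("greedy", "exact")) {
  mode <- match.arg(mode)
  len <- as.integer(len)
  if (len < 2L) stop("len must be >= 2")
  runs <- find_runs(seq, min_length = 1L)
  runs <- runs[runs$base == toupper(base), , drop = FALSE]
  if (mode == "greedy") as.integer(sum(runs$length %/% len))
  else as.integer(sum(runs$length == len))
}

# Strand-aware window sequences: reverse complement for minus-strand windows
# so every sequence reads in the non-template (transcript-sense) orientation.
extract_window_seqs <- function(genome, windows) {
  vapply(seq_along(windows), function(i) {
    chrom <- as.character(seqnames(windows))[i]
    s <- as.character(Biostrings::subseq(genome[[chrom]],
                                         start(windows)[i], end(windows)[i]))
    if (as.character(strand(windows))[i] == "-")
      s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    s
  }, character(1))
}

#' Homopolymer motif frequencies over a set of windows
#'
#' For each base and motif length, counts non-overlapping consecutive-
#' nucleotide motifs across a set of equal-width windows and reports the
#' frequency as motif count divided by the number of windows. Window
#' sequences are extracted strand-aware (minus-strand windows are reverse
#' complemented), so for windows centered on transcript 3' ends the counts
#' describe the non-template strand. Windows overrunning a chromosome end
#' are dropped with a message.
#'
#' @param genome A \code{DNAStringSet}.
#' @param windows A stranded \code{GRanges} of equal-width windows.
#' @param lengths Motif lengths to tabulate (default 2:10).
#' @param bases Bases to tabulate (default all four).
#' @param mode Counting mode passed to \code{\link{count_nonoverlapping}}.
#' @return Data frame with columns \code{base}, \code{length}, \code{count},
#'   \code{n_windows}, \code{frequency}.
#' @export
window_track_frequencies <- function(genome, windows, lengths = 2:10,
                                     bases = c("A", "C", "G", "T"),
                                     mode = c("greedy", "exact")) {
  mode <- match.arg(mode)
  if (length(windows) == 0L) stop("empty window set")
  if (length(unique(width(windows))) != 1L)
    stop("windows must all have the same width")
  sl <- setNames(Biostrings::width(genome), names(genome))
  inside <- start(windows) >= 1L &
    end(windows) <= sl[as.character(seqnames(windows))]
  if (any(!inside))
    message(sum(!inside), " window(s) overrun chromosome ends; dropped")
  windows <- windows[inside]
  if (length(windows) == 0L) stop("no windows left after dropping out-of-bounds")
  seqs <- extract_window_seqs(genome, windows)
  grid <- expand.grid(base = bases, length = lengths,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$count <- mapply(function(b, l)
    sum(vapply(seqs, count_nonoverlapping, integer(1), base = b, len = l,
               mode = mode)),
    grid$base, grid$length)
  grid$n_windows <- length(windows)
  grid$frequency <- grid$count / grid$n_windows
  grid[order(grid$base, grid$length), , drop = FALSE]
}

#' Windows centered on transcript end sites
#'
#' Builds fixed-width windows around each transcript's TES in transcription
#' direction. With the default width 40 the window covers TES-19..TES+20
#' transcribed-strand coordinates.
#'
#' @param transcripts A stranded \code{GRanges}.
#' @param width Window width in bases (default 40).
#' @return A stranded \code{GRanges} of windows.
#' @export
tes_windows <- function(transcripts, width = 40L) {
  p <- tes(transcripts)
  s <- as.character(strand(transcripts))
  up <- width %/% 2L - 1L   # bases before the TES along transcription
  dn <- width - up - 1L     # bases after
  st <- ifelse(s == "+", p - up, p - dn)
  GRanges(seqnames(transcripts), IRanges(st, st + width - 1L),
          strand = s)
}

#' Sample random gene-body windows
#'
#' Draws windows of the given width uniformly within each transcript body,
#' excluding starts whose window center lies within \code{width/2} of the
#' TES (so body windows do not overlap the 3'-end signal being contrasted).
#' If the exclusion leaves no candidate (e.g. the transcript is exactly one
#' window long), the exclusion is waived for that transcript. Transcripts
#' shorter than \code{width} are skipped with a warning.
#'
#' @param transcripts A stranded \code{GRanges}.
#' @param width Window width (default 40).
#' @param n_per_transcript Windows drawn per transcript (default 1).
#' @param seed Integer seed for reproducibility.
#' @return A stranded \code{GRanges} of sampled windows.
#' @export
sample_body_windows <- function(transcripts, width = 40L,
                                n_per_transcript = 1L, seed = 1L) {
  set.seed(seed)
  too_short <- width(transcripts) < width
  if (any(too_short))
    warning(sum(too_short), " transcript(s) shorter than ", width,
            " bp skipped")
  txs <- transcripts[!too_short]
  if (length(txs) == 0L) stop("no transcript long enough for body windows")
  t_pos <- tes(txs)
  rows <- lapply(seq_along(txs), function(i) {
    cand <- start(txs)[i]:(end(txs)[i] - width + 1L)
    centers <- cand + (width - 1L) %/% 2L
    ok <- abs(centers - t_pos[i]) >= width / 2
    if (!any(ok)) ok <- rep(TRUE, length(cand))
    starts <- sample(rep(cand[ok], 2L), n_per_transcript, replace = TRUE)
    data.frame(chrom = as.character(seqnames(txs))[i], start = starts,
               strand = as.character(strand(txs))[i])
  })
  df <- do.call(rbind, rows)
  GRanges(df$chrom, IRanges(df$start, df$start + width - 1L), strand = df$strand)
}

#' Locate the poly-tract anchor in a window
#'
#' Among maximal runs of \code{base} with length at least \code{anchor_min}
#' (the >5-mer rule: runs of 6 or more), returns the 1-based start of the
#' longest; ties are broken by the leftmost start. Intended for anchoring
#' metagene profiles on poly(T/A/G/C) tracts in windows around annotated
#' 3'-end sites; shorter repeats (>2-mers, i.e. \code{report_min} = 3) are
#' recorded en route via \code{\link{find_runs}}.
#'
#' @param seq A single string over \{A,C,G,T,N\}.
#' @param base The tract base.
#' @param report_min Minimum run length considered a repeat (default 3).
#' @param anchor_min Minimum run length to qualify as an anchor (default 6).
#' @return Integer start position, or \code{NA_integer_} if no run
#'   qualifies.
#' @export
locate_polytract_anchor <- function(seq, base, report_min = 3L, anchor_min = 6L) {
  runs <- find_runs(seq, min_length = report_min)
  runs <- runs[runs$base == toupper(base) & runs$length >= anchor_min, ,
               drop = FALSE]
  if (nrow(runs) == 0L) return(NA_integer_)
  best <- which(runs$length == max(runs$length))[1L]
  runs$start[best]
}
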