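#' Configuration for the synthetic termination-signal dataset
#'
#' The generator emulates the statistical structure the termination
#' analyses assume: a multi-chromosome genome of i.i.d. bases with
#' controllable GC content; non-overlapping stranded transcripts placed
#' alternately on both strands; a fraction of transcripts given a planted
#' poly-T tract on the non-template strand a few bases downstream of the
#' TES (equivalently a poly-A tract on the template strand — the
#' termination signal); and a NET-seq-like single-base 3'-end count signal
#' whose mean decays geometrically with distance upstream of the TES, plus
#' uniform Poisson body noise.
#'
#' @param seed Integer seed; all randomness flows from it.
#' @param n_chromosomes,chromosome_length Genome shape (default 2 x 1 Mb).
#' @param gc_content Background GC fraction (default 0.36, Arabidopsis-like).
#' @param n_transcripts Number of transcripts (default 500).
#' @param transcript_length_range Min/max transcript length (default 200-2000).
#' @param planted_fraction Fraction of transcripts receiving a tract
#'   (default 0.8).
#' @param tract_length_range Min/max planted tract length (default 6-12).
#' @param tract_offset_range Min/max offset of the tract start downstream of
#'   the TES, in bases (default 0-10; offset 0 starts at TES+1).
#' @param signal_peak_mean Poisson mean of the 3'-end count at the TES
#'   (default 50).
#' @param signal_decay Geometric decay q of the peak mean per base upstream
#'   of the TES (default 0.8).
#' @param body_noise_rate Uniform Poisson mean per transcript base
#'   (default 0.05).
#' @return An object of class \code{synth_config}.
#' @export
synth_config <- function(seed = 1L, n_chromosomes = 2L,
                         chromosome_length = 1e6, gc_content = 0.36,
                         n_transcripts = 500L,
                         transcript_length_range = c(200L, 2000L),
                         planted_fraction = 0.8,
                         tract_length_range = c(6L, 12L),
                         tract_offset_range = c(0L, 10L),
                         signal_peak_mean = 50, signal_decay = 0.8,
                         body_noise_rate = 0.05) {
  stopifnot(gc_content > 0, gc_content < 1,
            planted_fraction >= 0, planted_fraction <= 1,
            signal_decay > 0, signal_decay < 1,
            transcript_length_range[1] <= transcript_length_range[2],
            tract_length_range[1] <= tract_length_range[2],
            tract_offset_range[1] <= tract_offset_range[2])
  structure(as.list(environment()), class = "synth_config")
}

sample_range <- function(range, n) {
  if (range[1] == range[2]) rep(as.integer(range[1]), n)
  else sample(range[1]:range[2], n, replace = TRUE)
}

#' Generate a synthetic dataset with planted termination signals
#'
#' Deterministic under \code{config$seed}. Transcripts are packed greedily
#' along each chromosome with 600-bp end margins and random 300-800 bp
#' gaps, alternating strands; an error is raised if they do not fit. For a
#' planted plus-strand transcript the poly-T tract is written onto the
#' forward (non-template) strand starting \code{offset + 1} bases after the
#' TES; for a minus-strand transcript the mirrored poly-A is written onto
#' the forward strand so the minus (non-template) strand carries poly-T.
#'
#' @param config A \code{\link{synth_config}}.
#' @return An object of class \code{synthetic_dataset}: \code{genome}
#'   (DNAStringSet), \code{transcripts} (GRanges with mcols \code{id},
#'   \code{tpm}, \code{planted}, \code{tract_start}, \code{tract_length}),
#'   \code{signal} (\code{\link{signal_track}}), \code{config}.
#' @export
synth_generate <- function(config = synth_config()) {
  set.seed(config$seed)
  n_chr <- config$n_chromosomes
  len <- as.integer(config$chromosome_length)
  chroms <- paste0("chr", seq_len(n_chr))
  p_gc <- config$gc_content / 2
  p_at <- (1 - config$gc_content) / 2
  seqs <- lapply(seq_len(n_chr), function(i)
    sample(c("A", "C", "G", "T"), len, replace = TRUE,
           prob = c(p_at, p_gc, p_gc, p_at)))
  names(seqs) <- chroms

  # transcript placement: round-robin over chromosomes, greedy packing
  n_tx <- config$n_transcripts
  per_chr <- diff(round(seq(0, n_tx, length.out = n_chr + 1)))
  margin <- 600L
  rows <- vector("list", n_tx)
  k <- 0L
  for (ci in seq_len(n_chr)) {
    pos <- margin + 1L
    lens <- sample_range(config$transcript_length_range, per_chr[ci])
    gaps <- sample(300:800, per_chr[ci], replace = TRUE)
    for (j in seq_len(per_chr[ci])) {
      if (pos + lens[j] - 1L > len - margin)
        stop("infeasible packing: too many/long transcripts for genome size")
      k <- k + 1L
      rows[[k]] <- data.frame(chrom = chroms[ci], start = pos,
                              end = pos + lens[j] - 1L,
                              strand = if (k %% 2L == 1L) "+" else "-")
      pos <- pos + lens[j] + gaps[j]
    }
  }
  df <- do.call(rbind, rows)
  tx <- GRanges(df$chrom, IRanges(df$start, df$end), strand = df$strand)
  mcols(tx)$id <- sprintf("tx%04d", seq_len(n_tx))
  mcols(tx)$tpm <- round(rlnorm(n_tx, meanlog = 3, sdlog = 1), 3)

  # plant poly-T tracts on the non-template strand downstream of the TES
  planted <- rep(FALSE, n_tx)
  planted[sample(n_tx, round(config$planted_fraction * n_tx))] <- TRUE
  tract_len <- ifelse(planted, sample_range(config$tract_length_range, n_tx), NA)
  tract_off <- ifelse(planted, sample_range(config$tract_offset_range, n_tx), NA)
  tract_start <- rep(NA_integer_, n_tx)   # genomic start of the tract
  t_pos <- tes(tx)
  s <- as.character(strand(tx))
  chrom_of <- as.character(seqnames(tx))
  for (i in which(planted)) {
    if (s[i] == "+") {
      st <- t_pos[i] + tract_off[i] + 1L
      seqs[[chrom_of[i]]][st:(st + tract_len[i] - 1L)] <- "T"
    } else {
      st <- t_pos[i] - tract_off[i] - tract_len[i]
      seqs[[chrom_of[i]]][st:(st + tract_len[i] - 1L)] <- "A"
    }
    tract_start[i] <- st
  }
  mcols(tx)$planted <- planted
  mcols(tx)$tract_start <- tract_start
  mcols(tx)$tract_length <- as.integer(tract_len)

  genome <- Biostrings::DNAStringSet(vapply(seqs, paste, character(1),
                                            collapse = ""))
  names(genome) <- chroms
  suppressWarnings(seqlengths(tx) <- setNames(rep(len, n_chr), chroms))

  # NET-seq-like 3'-end signal: Poisson, geometric decay upstream of TES
  fwd <- rev <- lapply(setNames(rep(len, n_chr), chroms), numeric)
  tx_start <- start(tx); tx_end <- end(tx)
  for (i in seq_len(n_tx)) {
    posns <- tx_start[i]:tx_end[i]
    d <- if (s[i] == "+") tx_end[i] - posns else posns - tx_start[i]
    mu <- config$signal_peak_mean * config$signal_decay^d + config$body_noise_rate
    counts <- rpois(length(posns), mu)
    if (s[i] == "+") fwd[[chrom_of[i]]][posns] <- fwd[[chrom_of[i]]][posns] + counts
    else rev[[chrom_of[i]]][posns] <- rev[[chrom_of[i]]][posns] + counts
  }
  structure(list(genome = genome, transcripts = tx,
                 signal = signal_track(fwd, rev), config = config),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf(paste0("synthetic_dataset: %d chromosome(s) x %d bp, ",
                     "%d transcripts (%d planted)\n"),
              length(x$genome), Biostrings::width(x$genome)[1],
              length(x$transcripts), sum(x$transcripts$planted)))
  invisible(x)
}

#' Truth table of a synthetic dataset
#'
#' @param dataset A \code{synthetic_dataset}.
#' @return Data frame with one row per transcript: coordinates, strand, TPM,
#'   planted flag, tract genomic start and length.
#' @export
synth_truth <- function(dataset) {
  tx <- dataset$transcripts
  data.frame(id = tx$id, chrom = as.character(seqnames(tx)),
             start = start(tx), end = end(tx),
             strand = as.character(strand(tx)), tpm = tx$tpm,
             planted = tx$planted, tract_start = tx$tract_start,
             tract_length = tx$tract_length, stringsAsFactors = FALSE)
}

#' Write a synthetic dataset to files
#'
#' Emits \code{genome.fa}, \code{transcripts.bed} (TPM in the score
#' column), \code{signal.fwd.bedgraph} / \code{signal.rev.bedgraph}, and
#' \code{truth.tsv}; all re-readable with the package's readers.
#'
#' @param dataset A \code{synthetic_dataset}.
#' @param dir Output directory (created if absent).
#' @return The directory, invisibly.
#' @export
synth_write <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(dataset$genome, file.path(dir, "genome.fa"))
  write_bed6(dataset$transcripts, file.path(dir, "transcripts.bed"))
  write_bedgraph(dataset$signal, file.path(dir, "signal"), strand_suffixing = TRUE)
  write.table(synth_truth(dataset), file.path(dir, "truth.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Derive a matched NET/RIP annotation pair from a synthetic dataset
#'
#' The dataset's transcripts play the NET-seq role: their 3' ends are the
#' precise termination positions, immediately upstream of any planted
#' tract. The RIP-seq-like cohort is the same set with the 3' end jittered
#' in transcription direction by an amount that keeps the NET TES inside
#' the RIP termination region (-50..+200 of the RIP TES), emulating the
#' coarser 3' ends of assembled polymerase-bound transcripts. Every NET
#' transcript's planted classification label is therefore \code{terminal}.
#'
#' @param dataset A \code{synthetic_dataset}.
#' @param seed Integer seed for the jitter.
#' @return List with stranded \code{GRanges} elements \code{net} and
#'   \code{rip}, each with \code{id} and \code{tpm}.
#' @export
synth_net_rip <- function(dataset, seed = 1L) {
  set.seed(seed)
  net <- dataset$transcripts
  mcols(net) <- mcols(net)[c("id", "tpm")]
  net$id <- sub("^tx", "net", net$id)
  # RIP TES = NET TES + delta along transcription; the NET TES lies in
  # [RIP TES - 50, RIP TES + 200] iff delta is in [-200, 50]; the lower
  # bound also keeps the jittered transcript non-degenerate
  lo <- -pmin(200L, width(net) - 10L)
  delta <- lo + floor(runif(length(net)) * (50L - lo + 1L))
  s <- as.character(strand(net))
  new_end <- ifelse(s == "+", end(net) + delta, end(net))
  new_start <- ifelse(s == "+", start(net), start(net) - delta)
  rip <- GRanges(seqnames(net), IRanges(new_start, new_end), strand = s)
  suppressWarnings(seqlengths(rip) <- seqlengths(net))
  mcols(rip)$id <- sub("^net", "rip", net$id)
  mcols(rip)$tpm <- net$tpm
  list(net = net, rip = rip)
}
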