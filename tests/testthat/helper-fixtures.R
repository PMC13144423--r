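# Shared helpers: tiny genomes, transcript sets and independent oracles.

suppressPackageStartupMessages(library(GenomicRanges))

toy_genome <- function(...) {
  seqs <- toupper(c(...))
  Biostrings::DNAStringSet(seqs)
}

# random ACGT string
random_seq <- function(n, alphabet = c("A", "C", "G", "T"), prob = NULL) {
  paste(sample(alphabet, n, replace = TRUE, prob = prob), collapse = "")
}

make_tx <- function(chrom, start, end, strand, id = NULL, tpm = NULL,
                    seqlen = NULL) {
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end),
                               strand = strand)
  GenomicRanges::mcols(gr)$id <-
    if (is.null(id)) sprintf("tx%d", seq_along(gr)) else id
  if (!is.null(tpm)) GenomicRanges::mcols(gr)$tpm <- tpm
  if (!is.null(seqlen))
    suppressWarnings(GenomeInfoDb::seqlengths(gr) <- seqlen)
  gr
}

anchors_of <- function(tx) {
  GenomicRanges::GRanges(GenomicRanges::seqnames(tx),
                         IRanges::IRanges(tes(tx), width = 1L),
                         strand = GenomicRanges::strand(tx))
}

# Independent scorer used as oracle: literal transcription of the printed
# formula, char-by-char, no shared code with the package internals.
oracle_score <- function(window, match) {
  b <- strsplit(window, "")[[1]]
  is_m <- b %in% match
  t <- 0; bonus <- 0; g <- 0
  run <- 0; gap <- 0
  for (i in seq_along(b)) {
    if (is_m[i]) {
      run <- run + 1
      gap <- 0
      t <- t + 1
      bonus <- bonus + (run - 1)   # 1 + 2 + ... + (x-1), incrementally
    } else {
      run <- 0
      gap <- gap + 1
      g <- max(g, gap)
    }
  }
  max(t + bonus - g, 0)
}

# strand-aware window extraction, written independently of the package path
extract_window_seqs_test <- function(genome, windows) {
  vapply(seq_along(windows), function(i) {
    chrom <- as.character(GenomicRanges::seqnames(windows))[i]
    s <- substr(as.character(genome[[chrom]]),
                GenomicRanges::start(windows)[i],
                GenomicRanges::end(windows)[i])
    if (as.character(GenomicRanges::strand(windows))[i] == "-")
      s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    s
  }, character(1))
}

# all length-w windows over the given alphabet
all_windows <- function(w, alphabet = c("A", "C", "G", "T")) {
  grid <- do.call(expand.grid, rep(list(alphabet), w))
  apply(as.matrix(grid), 1, paste, collapse = "")
}
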