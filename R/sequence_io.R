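#' Read a genome FASTA into a DNAStringSet
#'
#' Sequence names are truncated at the first whitespace, bases are uppercased
#' (softmasking is ignored: the scores here depend on base composition only),
#' and any IUPAC ambiguity code other than A/C/G/T is mapped to N with a
#' warning.
#'
#' @param path Path to a FASTA file.
#' @return A \link[Biostrings]{DNAStringSet} over the alphabet \{A,C,G,T,N\}.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L) stop("FASTA file is empty: ", path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(names(seqs)))
    stop("duplicate FASTA headers: ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  chr <- toupper(as.character(seqs))
  n_amb <- sum(vapply(chr, function(s)
    sum(strsplit(s, "")[[1]] %in% c("A", "C", "G", "T", "N") == FALSE),
    integer(1)))
  if (n_amb > 0L) {
    warning(n_amb, " non-ACGTN base(s) mapped to N")
    chr <- vapply(chr, function(s)
      gsub("[^ACGTN]", "N", s), character(1), USE.NAMES = FALSE)
  }
  out <- Biostrings::DNAStringSet(chr)
  names(out) <- names(seqs)
  out
}

#' Write a genome to FASTA
#'
#' @param genome A \code{DNAStringSet}.
#' @param path Output path.
#' @export
write_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path, width = 70L)
  invisible(path)
}

#' Read transcripts from a 6-column BED file
#'
#' Returns a \code{GRanges} (1-based, closed; converted from BED's 0-based
#' half-open coordinates by rtracklayer) with metadata columns \code{id} and,
#' when \code{tpm_from_score} is set, \code{tpm} taken from BED column 5.
#' Records without a definite strand are rejected: every downstream analysis
#' here is strand-specific.
#'
#' @param path Path to a BED6 file.
#' @param tpm_from_score Interpret BED column 5 as TPM (default \code{FALSE}).
#' @param genome Optional \code{DNAStringSet}; when supplied, chromosome names
#'   are validated against it and seqlengths attached.
#' @return A \code{GRanges} with \code{id} (and optionally \code{tpm}) mcols.
#' @export
read_bed6 <- function(path, tpm_from_score = FALSE, genome = NULL) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  gr <- rtracklayer::import(path, format = "BED")
  if (is.null(gr$name)) stop("BED file must have 6 columns (name, score, strand)")
  if (any(as.character(strand(gr)) == "*"))
    stop("BED records with strand '.' are not allowed; transcripts must be stranded")
  mcols(gr)$id <- gr$name
  if (tpm_from_score) {
    mcols(gr)$tpm <- gr$score
  }
  mcols(gr) <- mcols(gr)[setdiff(names(mcols(gr)), c("name", "score"))]
  if (!is.null(genome)) {
    missing_chr <- setdiff(as.character(unique(seqnames(gr))), names(genome))
    if (length(missing_chr))
      stop("BED chromosomes absent from genome: ",
           paste(missing_chr, collapse = ", "))
    sl <- setNames(Biostrings::width(genome), names(genome))
    GenomeInfoDb::seqlevels(gr) <- names(genome)
    suppressWarnings(seqlengths(gr) <- sl)
    if (any(end(gr) > sl[as.character(seqnames(gr))]))
      stop("BED record extends past chromosome end")
  }
  gr
}

#' Write transcripts to BED6
#'
#' The \code{tpm} metadata column (if present) is written to the BED score
#' column; otherwise score is 0.
#'
#' @param gr A stranded \code{GRanges} with an \code{id} metadata column.
#' @param path Output path.
#' @export
write_bed6 <- function(gr, path) {
  out <- gr
  mcols(out) <- NULL
  out$name <- gr$id
  out$score <- if (!is.null(gr$tpm)) gr$tpm else 0
  rtracklayer::export(out, path, format = "BED")
  invisible(path)
}

#' Read transcript-level intervals from a minimal GTF
#'
#' Only rows with feature type \code{transcript} are used; exon structure is
#' ignored — the analyses here are transcript-granular. The
#' \code{transcript_id} attribute becomes \code{id}; a \code{TPM} attribute,
#' when present, becomes \code{tpm}.
#'
#' @param path Path to a GTF file.
#' @return A \code{GRanges} with \code{id} (and possibly \code{tpm}) mcols.
#' @export
read_gtf_transcripts <- function(path) {
  if (!file.exists(path)) stop("GTF file not found: ", path)
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "transcript"]
  if (length(gr) == 0L) stop("GTF contains no 'transcript' features")
  mcols(gr)$id <- gr$transcript_id
  keep <- c("id", if ("TPM" %in% names(mcols(gr))) "TPM")
  mcols(gr) <- mcols(gr)[keep]
  if ("TPM" %in% names(mcols(gr))) {
    mcols(gr)$tpm <- as.numeric(mcols(gr)$TPM)
    mcols(gr)$TPM <- NULL
  }
  gr
}

#' Transcript end site (TES) of stranded transcripts
#'
#' The last transcribed base: \code{end} for plus-strand transcripts,
#' \code{start} for minus-strand transcripts (1-based).
#'
#' @param gr A stranded \code{GRanges}.
#' @return Integer vector of genomic positions.
#' @export
tes <- function(gr) {
  s <- as.character(strand(gr))
  if (any(s == "*")) stop("TES undefined for unstranded intervals")
  ifelse(s == "+", end(gr), start(gr))
}

#' Transcript start site (TSS) of stranded transcripts
#'
#' @param gr A stranded \code{GRanges}.
#' @return Integer vector of genomic positions.
#' @export
tss <- function(gr) {
  s <- as.character(strand(gr))
  if (any(s == "*")) stop("TSS undefined for unstranded intervals")
  ifelse(s == "+", start(gr), end(gr))
}

#' Per-base, per-strand signal container
#'
#' A light container for per-base numeric values over a genome, one vector
#' per chromosome and strand (forward/reverse). \code{NA} marks positions
#' with no defined value (e.g. within half a window of a chromosome end for
#' score tracks); it is distinct from 0, which is a meaningful value.
#'
#' @param fwd,rev Named lists of numeric vectors, one per chromosome; each
#'   vector's length is the chromosome length.
#' @return An object of class \code{signal_track}.
#' @export
signal_track <- function(fwd, rev) {
  stopifnot(identical(names(fwd), names(rev)))
  stopifnot(all(lengths(fwd) == lengths(rev)))
  structure(list(fwd = fwd, rev = rev,
                 seqlengths = setNames(lengths(fwd), names(fwd))),
            class = "signal_track")
}

#' @export
print.signal_track <- function(x, ...) {
  cat("signal_track:", length(x$fwd), "chromosome(s),",
      sum(x$seqlengths), "bases per strand\n")
  invisible(x)
}

track_vector <- function(track, chrom, strand) {
  side <- if (strand %in% c("+", "fwd", "forward")) "fwd" else "rev"
  v <- track[[side]][[chrom]]
  if (is.null(v)) stop("no track for chromosome ", chrom)
  v
}

#' Write one strand of a signal track as bedGraph
#'
#' Adjacent equal-valued positions are merged into maximal intervals;
#' \code{NA} positions are omitted from the file. With
#' \code{strand_suffixing}, both strands are written as
#' \code{<path>.fwd.bedgraph} and \code{<path>.rev.bedgraph}.
#'
#' @param track A \code{signal_track}.
#' @param path Output path (or path prefix when \code{strand_suffixing}).
#' @param strand Which strand to write (\code{"fwd"} or \code{"rev"}) when
#'   \code{strand_suffixing} is \code{FALSE}.
#' @param strand_suffixing Write both strands to suffixed files.
#' @export
write_bedgraph <- function(track, path, strand = "fwd", strand_suffixing = FALSE) {
  if (strand_suffixing) {
    write_bedgraph(track, paste0(path, ".fwd.bedgraph"), "fwd")
    write_bedgraph(track, paste0(path, ".rev.bedgraph"), "rev")
    return(invisible(path))
  }
  pieces <- lapply(names(track$fwd), function(chrom) {
    v <- track_vector(track, chrom, strand)
    if (length(v) == 0L) return(NULL)
    r <- rle(ifelse(is.na(v), NA, v))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- !is.na(r$values)
    if (!any(keep)) return(NULL)
    data.frame(chrom = chrom, start = starts[keep], end = ends[keep],
               score = r$values[keep])
  })
  df <- do.call(rbind, pieces)
  if (is.null(df) || nrow(df) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  gr <- GRanges(df$chrom, IRanges(df$start, df$end), score = df$score)
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Read a bedGraph file into per-base vectors
#'
#' @param path Path to a bedGraph file.
#' @param seqlengths Named integer vector of chromosome lengths.
#' @param missing Fill value for positions not covered by the file
#'   (\code{NA} by default; use 0 for count tracks).
#' @return Named list of per-base numeric vectors.
#' @export
read_bedgraph <- function(path, seqlengths, missing = NA_real_) {
  out <- lapply(seqlengths, function(n) rep(missing, n))
  if (file.size(path) > 0L) {
    gr <- rtracklayer::import(path, format = "bedGraph")
    bad <- setdiff(unique(as.character(seqnames(gr))), names(out))
    if (length(bad)) stop("bedGraph chromosome not in seqlengths: ", bad[1])
    for (chrom in unique(as.character(seqnames(gr)))) {
      sub <- gr[seqnames(gr) == chrom]
      idx <- sequence(width(sub), from = start(sub))
      out[[chrom]][idx] <- rep(sub$score, width(sub))
    }
  }
  out
}
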