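#' Filter transcripts by abundance and length
#'
#' Retains transcripts with TPM strictly greater than \code{min_tpm} and
#' length strictly less than \code{max_length} (the assembly filters:
#' TPM > 5 and length < 5000 bp for NET-seq transcripts, TPM > 1 and
#' length < 5000 bp for RIP-seq transcripts). Order is preserved.
#'
#' @param transcripts A \code{GRanges} with a \code{tpm} metadata column.
#' @param min_tpm Strict lower bound on TPM.
#' @param max_length Strict upper bound on transcript length in bases.
#' @return The filtered \code{GRanges}.
#' @export
filter_transcripts <- function(transcripts, min_tpm = 5, max_length = 5000) {
  if (is.null(transcripts$tpm) || anyNA(transcripts$tpm))
    stop("all transcripts must carry a tpm value")
  transcripts[transcripts$tpm > min_tpm & width(transcripts) < max_length]
}

#' Termination regions around transcript 3' ends
#'
#' For each transcript, the interval from \code{upstream} bases before to
#' \code{downstream} bases after its TES, in transcription direction
#' (defaults -50/+200, a 251-bp region). On the minus strand the region is
#' mirrored in genome coordinates. Regions are clipped to chromosome bounds
#' with a warning when \code{seqlengths} are available.
#'
#' @param transcripts A stranded \code{GRanges} with an \code{id} mcol.
#' @param upstream Bases upstream of the TES (default 50).
#' @param downstream Bases downstream of the TES (default 200).
#' @return A stranded \code{GRanges} with mcol \code{source_transcript_id}.
#' @export
make_termination_regions <- function(transcripts, upstream = 50L,
                                     downstream = 200L) {
  p <- tes(transcripts)
  s <- as.character(strand(transcripts))
  st <- ifelse(s == "+", p - upstream, p - downstream)
  en <- ifelse(s == "+", p + downstream, p + upstream)
  sl <- seqlengths(transcripts)
  chr <- as.character(seqnames(transcripts))
  clipped <- st < 1L
  st <- pmax(st, 1L)
  if (!all(is.na(sl))) {
    lim <- unname(sl[chr])
    clipped <- clipped | (!is.na(lim) & en > lim)
    en <- ifelse(is.na(lim), en, pmin(en, lim))
  }
  if (any(clipped))
    warning(sum(clipped), " termination region(s) clipped at chromosome ends")
  out <- GRanges(chr, IRanges(st, en), strand = s)
  suppressWarnings(seqlengths(out) <- sl)
  mcols(out)$source_transcript_id <-
    if (!is.null(transcripts$id)) transcripts$id else as.character(seq_along(transcripts))
  out
}

#' Classify nascent transcripts by 3'-end location
#'
#' Labels each NET transcript: \code{terminal} if its TES lies within any
#' same-strand termination region (region boundaries included), else
#' \code{body} if its interval is wholly contained in a same-strand RIP
#' transcript, else \code{unassigned}. Terminal takes precedence over body;
#' the labels partition the NET set. When a TES overlaps several regions the
#' first in genome order is recorded as the match.
#'
#' @param net A stranded \code{GRanges} of NET transcripts with \code{id}.
#' @param rip A stranded \code{GRanges} of RIP transcripts with \code{id}.
#' @param regions Termination regions; computed from \code{rip} with the
#'   default -50/+200 offsets when omitted.
#' @return Data frame with columns \code{id}, \code{label},
#'   \code{matched_rip_id}; label counts attached as attribute
#'   \code{"counts"}.
#' @export
classify_net_transcripts <- function(net, rip, regions = NULL) {
  if (length(net) == 0L) stop("classification stage: empty NET transcript set")
  if (is.null(regions)) regions <- make_termination_regions(rip)
  net_id <- if (!is.null(net$id)) net$id else as.character(seq_along(net))
  tes_gr <- GRanges(seqnames(net), IRanges(tes(net), width = 1L),
                    strand = strand(net))
  ord <- order(as.factor(seqnames(regions)), start(regions))
  regions_sorted <- regions[ord]
  hits_term <- findOverlaps(tes_gr, regions_sorted, ignore.strand = FALSE)
  first_term <- tapply(subjectHits(hits_term), queryHits(hits_term), min)
  hits_body <- findOverlaps(net, rip, type = "within", ignore.strand = FALSE)
  first_body <- tapply(subjectHits(hits_body), queryHits(hits_body), min)

  label <- rep("unassigned", length(net))
  matched <- rep(NA_character_, length(net))
  ti <- as.integer(names(first_term))
  label[ti] <- "terminal"
  matched[ti] <- regions_sorted$source_transcript_id[first_term]
  bi <- setdiff(as.integer(names(first_body)), ti)
  label[bi] <- "body"
  rip_id <- if (!is.null(rip$id)) rip$id else as.character(seq_along(rip))
  matched[bi] <- rip_id[first_body[as.character(bi)]]

  out <- data.frame(id = net_id, label = label, matched_rip_id = matched,
                    stringsAsFactors = FALSE)
  attr(out, "counts") <- c(terminal = sum(label == "terminal"),
                           body = sum(label == "body"),
                           unassigned = sum(label == "unassigned"))
  out
}
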