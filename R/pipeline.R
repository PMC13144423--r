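#' Default pipeline parameters
#'
#' The defaults reproduce the published analysis settings: 7-bp scoring
#' windows (half-width 3), termination regions -50/+200 around the RIP TES,
#' 40-bp homopolymer windows, 50-bp Welch flanks, 5-bp profile bins, and
#' the assembly filters TPM > 5 & length < 5000 (NET) and TPM > 1 &
#' length < 5000 (RIP).
#'
#' @param half_width Scoring half-window.
#' @param upstream,downstream Termination-region offsets around the TES.
#' @param track_window Homopolymer window width.
#' @param flank Welch flank width.
#' @param bin_width Metagene bin width.
#' @param metagene_span Bases either side of the TES in the profile.
#' @param net_min_tpm,rip_min_tpm,max_length Transcript filters.
#' @param track_lengths Homopolymer motif lengths tabulated.
#' @return Named list of parameters.
#' @export
pipeline_params <- function(half_width = 3L, upstream = 50L, downstream = 200L,
                            track_window = 40L, flank = 50L, bin_width = 5L,
                            metagene_span = 300L,
                            net_min_tpm = 5, rip_min_tpm = 1,
                            max_length = 5000, track_lengths = 2:10) {
  as.list(environment())
}

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Run the full termination analysis on one dataset
#'
#' Executes, in order: transcript filtering (NET and RIP), termination
#' region construction, NET 3'-end classification, genome-wide T-score
#' scoring, the non-template-strand TES metagene with the Welch flank
#' comparison, and the TES-versus-body homopolymer track frequencies.
#' Writes \code{labels.tsv}, \code{tes_profile.tsv}, \code{flank_test.json},
#' \code{freq_tes.tsv}, \code{freq_body.tsv}, and \code{manifest.json}
#' (parameter echoes, seed and per-stage record counts; written even when a
#' stage fails, with the failing stage recorded). Deterministic under
#' \code{seed}.
#'
#' @param genome A \code{DNAStringSet}.
#' @param net,rip Stranded \code{GRanges} with \code{id} and \code{tpm}.
#' @param out_dir Output directory.
#' @param params \code{\link{pipeline_params}}.
#' @param seed Integer seed (body-window sampling).
#' @return Invisible list with the classification, flank comparison, profile
#'   and frequency tables.
#' @export
run_pipeline <- function(genome, net, rip, out_dir,
                         params = pipeline_params(), seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package_version = as.character(utils::packageVersion("polvterm")),
                   seed = seed, params = params, stages = list())
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) {
      manifest$failed_stage <<- name
      write_json_file(manifest, file.path(out_dir, "manifest.json"))
      stop("stage '", name, "': ", conditionMessage(e), call. = FALSE)
    })
    res
  }

  net_f <- stage("filter_net",
                 filter_transcripts(net, params$net_min_tpm, params$max_length))
  rip_f <- stage("filter_rip",
                 filter_transcripts(rip, params$rip_min_tpm, params$max_length))
  manifest$stages$filter <- list(net_in = length(net), net_kept = length(net_f),
                                 rip_in = length(rip), rip_kept = length(rip_f))

  regions <- stage("termination_regions",
                   make_termination_regions(rip_f, params$upstream,
                                            params$downstream))
  manifest$stages$regions <- list(n = length(regions))

  labels <- stage("classification",
                  classify_net_transcripts(net_f, rip_f, regions))
  manifest$stages$classification <- as.list(attr(labels, "counts"))
  write.table(labels, file.path(out_dir, "labels.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  tscore <- stage("scoring",
                  score_genome(genome, scoring_config("T", params$half_width)))

  terminal <- net_f[labels$label == "terminal"]
  anchors_src <- if (length(terminal) >= 2L) terminal else net_f
  anchors <- GRanges(seqnames(anchors_src),
                     IRanges(tes(anchors_src), width = 1L),
                     strand = strand(anchors_src))
  prof <- stage("metagene", {
    mat <- extract_matrix(tscore, anchors, L = params$metagene_span,
                          R = params$metagene_span)
    metagene_profile(mat, params$bin_width)
  })
  write.table(prof, file.path(out_dir, "tes_profile.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  fc <- stage("flank_test", flank_test(tscore, anchors, params$flank))
  manifest$stages$metagene <- list(anchors = fc$n)
  write_json_file(list(test = fc$test, flank = fc$flank, n = fc$n,
                       upstream_mean = fc$upstream_mean,
                       downstream_mean = fc$downstream_mean,
                       t_statistic = fc$t_statistic, p_value = fc$p_value),
                  file.path(out_dir, "flank_test.json"))

  freqs <- stage("track_frequencies", {
    tes_w <- tes_windows(anchors_src, params$track_window)
    body_w <- sample_body_windows(anchors_src, params$track_window, seed = seed)
    list(tes = window_track_frequencies(genome, tes_w, params$track_lengths),
         body = window_track_frequencies(genome, body_w, params$track_lengths))
  })
  write.table(freqs$tes, file.path(out_dir, "freq_tes.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(freqs$body, file.path(out_dir, "freq_body.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  manifest$stages$track_frequencies <-
    list(tes_windows = freqs$tes$n_windows[1], body_windows = freqs$body$n_windows[1])

  write_json_file(manifest, file.path(out_dir, "manifest.json"))
  invisible(list(labels = labels, profile = prof, flank = fc, freqs = freqs,
                 manifest = manifest))
}
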