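#!/usr/bin/env Rscript
# Strand-aware metagene of the non-template-strand T-score around transcript
# end sites, with the Welch comparison of the 50-bp flanks upstream versus
# downstream of the TES, and the distribution of the per-transcript maximum
# NET-signal position. If poly-T tracts terminate transcription, the
# non-template T-score should step up immediately after the TES and the
# NET-signal maxima should sit at the transcript ends.

source("analysis/00_config.R")

ds <- study_dataset()
tscore <- score_genome(ds$genome, scoring_config("T"))
anchors <- GenomicRanges::GRanges(GenomicRanges::seqnames(ds$transcripts),
                                  IRanges::IRanges(tes(ds$transcripts), width = 1),
                                  strand = GenomicRanges::strand(ds$transcripts))

mat <- extract_matrix(tscore, anchors, L = 300, R = 300)
prof <- metagene_profile(mat, bin_width = 5)
write.table(prof, file.path(RESULTS_DIR, "05_tes_profile.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
up_bins <- prof$mean[prof$bin_center < 0 & prof$bin_center >= -50]
dn_bins <- prof$mean[prof$bin_center > 0 & prof$bin_center <= 50]
message(sprintf("profile means near TES: upstream %.3f, downstream %.3f",
                mean(up_bins), mean(dn_bins)))

fc <- flank_test(tscore, anchors, flank = 50)
print(fc)
jsonlite::write_json(list(test = fc$test, flank = fc$flank, n = fc$n,
                          upstream_mean = fc$upstream_mean,
                          downstream_mean = fc$downstream_mean,
                          t_statistic = fc$t_statistic,
                          p_value = fc$p_value),
                     file.path(RESULTS_DIR, "05_flank_test.json"),
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)

pos <- max_signal_positions(ds$signal, ds$transcripts)
dist_tab <- data.frame(decile = sprintf("(%.1f,%.1f]", (0:9) / 10, (1:10) / 10),
                       n = as.integer(table(cut(pos, breaks = (0:10) / 10))))
write.table(dist_tab, file.path(RESULTS_DIR, "05_max_signal_position.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
message(sprintf("fraction of transcripts with their signal maximum in the top decile: %.3f",
                mean(pos > 0.9)))
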