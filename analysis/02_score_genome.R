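#!/usr/bin/env Rscript
# Genome-wide T-score on both strands. The score of a position is computed
# from the 7-bp window centered on it: number of Ts, plus 1+2+...+(x-1) for
# every run of x consecutive Ts, minus the longest run of consecutive
# non-Ts, clamped at zero. Forward-strand scores report runs of T on the
# forward strand; reverse-strand scores report runs of T on the reverse
# strand (runs of A on the forward sequence).

source("analysis/00_config.R")

ds <- study_dataset()
tscore <- score_genome(ds$genome, scoring_config("T"), verbose = TRUE)
atscore <- score_genome(ds$genome, scoring_config(c("A", "T")))

dir.create(SCRATCH_DIR, showWarnings = FALSE, recursive = TRUE)
write_bedgraph(tscore, file.path(SCRATCH_DIR, "tscore"), strand_suffixing = TRUE)
message("T-score tracks written to ", SCRATCH_DIR)

per_chrom <- do.call(rbind, lapply(names(tscore$fwd), function(ch) {
  data.frame(chrom = ch,
             t_fwd_mean = mean(tscore$fwd[[ch]], na.rm = TRUE),
             t_rev_mean = mean(tscore$rev[[ch]], na.rm = TRUE),
             at_mean = mean(atscore$fwd[[ch]], na.rm = TRUE),
             t_fwd_max = max(tscore$fwd[[ch]], na.rm = TRUE))
}))
write.table(per_chrom, file.path(RESULTS_DIR, "02_score_summary.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
print(per_chrom)
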