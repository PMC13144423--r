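#!/usr/bin/env Rscript
# Homopolymer track frequencies at transcript 3' ends versus gene bodies.
# 40-bp non-template-strand windows centered on the TES are contrasted with
# random 40-bp windows inside transcript bodies; for each base and motif
# length, the number of non-overlapping consecutive-nucleotide motifs per
# window is reported. With planted poly-T tracts the T 8-mer frequency at
# the 3' end should dwarf the body background.

source("analysis/00_config.R")

ds <- study_dataset()
tx <- ds$transcripts

f_tes <- window_track_frequencies(ds$genome, tes_windows(tx, 40), lengths = 2:10)
f_body <- window_track_frequencies(
  ds$genome, sample_body_windows(tx, 40, seed = STUDY_SEED), lengths = 2:10)

write.table(f_tes, file.path(RESULTS_DIR, "04_freq_tes.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(f_body, file.path(RESULTS_DIR, "04_freq_body.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

t8_tes <- f_tes$frequency[f_tes$base == "T" & f_tes$length == 8]
t8_body <- f_body$frequency[f_body$base == "T" & f_body$length == 8]
message(sprintf("T 8-mer frequency: TES windows %.4f vs body windows %.4f (ratio %s)",
                t8_tes, t8_body,
                if (t8_body > 0) sprintf("%.1f", t8_tes / t8_body) else ">1000"))
other8 <- f_tes$frequency[f_tes$length == 8 & f_tes$base != "T"]
message("8-mer frequencies of A/C/G at the TES: ",
        paste(sprintf("%.4f", other8), collapse = ", "))
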