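#!/usr/bin/env Rscript
# Termination-region classification. The synthetic transcripts play the
# NET-seq role (precise 3' ends); a jittered copy plays the RIP-seq role
# (approximate assembled 3' ends). After the abundance/length filters
# (TPM > 5 & < 5000 bp for NET, TPM > 1 & < 5000 bp for RIP), each NET
# transcript is labelled terminal if its TES falls in a same-strand
# -50..+200 region around a RIP TES, body if it is nested in a same-strand
# RIP transcript, and unassigned otherwise.

source("analysis/00_config.R")

ds <- study_dataset()
pair <- study_cohorts(ds)

net_f <- filter_transcripts(pair$net, min_tpm = 5, max_length = 5000)
rip_f <- filter_transcripts(pair$rip, min_tpm = 1, max_length = 5000)
message("filters kept ", length(net_f), "/", length(pair$net), " NET and ",
        length(rip_f), "/", length(pair$rip), " RIP transcripts")

regions <- make_termination_regions(rip_f)
cls <- classify_net_transcripts(net_f, rip_f, regions)
print(attr(cls, "counts"))

write.table(cls, file.path(RESULTS_DIR, "03_labels.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
counts <- attr(cls, "counts")
write.table(data.frame(label = names(counts), n = as.integer(counts)),
            file.path(RESULTS_DIR, "03_label_counts.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
message("every filtered NET 3' end is expected to be terminal by construction: ",
        counts["terminal"] == length(net_f))
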