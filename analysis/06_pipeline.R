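#!/usr/bin/env Rscript
# One-call version of scripts 03-05: runs the full filter -> regions ->
# classification -> scoring -> metagene/flank-test -> track-frequency
# sequence with the published parameter defaults and a run manifest.

source("analysis/00_config.R")

ds <- study_dataset()
pair <- study_cohorts(ds)
res <- run_pipeline(ds$genome, pair$net, pair$rip,
                    out_dir = file.path(RESULTS_DIR, "pipeline"),
                    seed = STUDY_SEED)
message("pipeline outputs in ", file.path(RESULTS_DIR, "pipeline"))
print(attr(res$labels, "counts"))
print(res$flank)
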