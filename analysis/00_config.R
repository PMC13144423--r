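# Shared settings for the analysis scripts. Every script regenerates the
# synthetic dataset deterministically from STUDY_SEED, so the scripts can be
# run independently or in order.

suppressPackageStartupMessages(library(polvterm))

STUDY_SEED <- 20260101L

# Study conditions: 2 x 1 Mb genome at Arabidopsis-like GC, 500 stranded
# transcripts, 80% carrying a planted poly-T tract (length 8, within 10 bp
# downstream of the TES) on the non-template strand, plus a NET-seq-like
# 3'-end count signal.
study_config <- function(seed = STUDY_SEED) {
  synth_config(seed = seed, tract_length_range = c(8L, 8L))
}

RESULTS_DIR <- "results"
SCRATCH_DIR <- "scratch/synthetic"
dir.create(RESULTS_DIR, showWarnings = FALSE, recursive = TRUE)

study_dataset <- function() synth_generate(study_config())

study_cohorts <- function(dataset) synth_net_rip(dataset, seed = STUDY_SEED)
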