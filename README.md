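# polvterm

Sequence-level analysis of RNA polymerase V transcription termination
signals.

In plants, RNA polymerase V (Pol V) transcribes the scaffold non-coding
RNAs of the RNA-directed DNA methylation (RdDM) pathway, so the sites
where Pol V terminates shape the genomic DNA methylation landscape. Pol V
terminates spontaneously over A-rich template DNA — read on the
non-template strand, a run of Ts just downstream of the transcript end
site (TES), and on the nascent RNA a 3' poly(U) stretch. This package is
for genomics analysts who want to score, locate and validate that signal
on a genome with stranded transcript annotations and per-base 3'-end
signal tracks.

## What it computes

**The T-score / AT-score.** For position *k*, over the 7-bp window
*k*−3..*k*+3, with *t* the number of matching bases (T, or A/T), *x_i* the
lengths of runs of consecutive matches and *g* the longest run of
consecutive non-matches:

    Score(k) = max( t + Σ_i x_i (x_i − 1)/2 − g , 0 )

so `TTTTTTT` scores 28 (= 7 + 21), `TTCCTTT` scores 7 (= 5 + 1 + 3 − 2),
and `CCTCCCC` clamps to 0 (= 1 + 0 − 4). Forward- and reverse-strand
tracks are computed separately; the reverse-strand score of a window is
the score of its reverse complement.

**Around it**, the package provides: FASTA/BED6/bedGraph/minimal-GTF I/O
(Biostrings/rtracklayer-backed, GRanges containers); homopolymer run
finding, non-overlapping ℓ-mer counting and 40-bp TES-versus-body window
frequencies; poly-tract anchoring (longest run ≥ 6, leftmost on ties);
transcript filtering (TPM > 5 & < 5000 bp NET, TPM > 1 & < 5000 bp RIP),
−50..+200 termination regions and terminal/body/unassigned classification
of NET 3' ends; strand-aware TES metagenes with 5-bp bins and a Welch
test of the 50-bp flanks; and a synthetic-genome generator that plants
poly-T tracts and NET-seq-like signal with full ground truth.

## Worked example

```r
library(polvterm)

# the score of single windows
score_window("TTTTTTT", scoring_config("T"))$score          # 28
score_window("TTCCTTT", scoring_config("T"))$score          # 7
score_window("ATATATA", scoring_config(c("A", "T")))$score  # 28

# a synthetic genome with planted 8-mer termination tracts (80% of 500
# transcripts), scored genome-wide, flank-tested at the TES
ds <- synth_generate(synth_config(seed = 101, tract_length_range = c(8, 8)))
tscore <- score_genome(ds$genome, scoring_config("T"))
tx <- ds$transcripts
anchors <- GenomicRanges::GRanges(GenomicRanges::seqnames(tx),
                                  IRanges::IRanges(tes(tx), width = 1),
                                  strand = GenomicRanges::strand(tx))
flank_test(tscore, anchors, flank = 50)
#> Welch two-sample t test (50-bp flanks, n = 500 anchors)
#>   upstream mean   = 1.2924
#>   downstream mean = 3.8308
#>   t = 31.6180, p = 2.246e-140
```

The upstream flank mean (~1.29) is the genomic background T-score; the
downstream step-up to ~3.83 is the planted non-template poly-T signal just
after the TES, and the Welch test on the 500 per-anchor flank means
rejects decisively — the termination pattern, recovered from sequence
alone. Running the same comparison with `planted_fraction = 0` gives a
two-sided p that behaves like a uniform draw (no signal).

The numbered scripts under `analysis/` run the full study on the
synthetic dataset — simulation, genome scoring, classification
(474/474 filtered NET transcripts recovered as terminal), track
frequencies (T 8-mer frequency 0.804 at TES windows versus 0.004 in
bodies), and the metagene/flank analysis — writing compact tables under
`results/`. Full-size FASTA/bedGraph intermediates go to `scratch/`.

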