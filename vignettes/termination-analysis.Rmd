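---
title: "Detecting A-rich-template termination signals of Pol V"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting A-rich-template termination signals of Pol V}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polvterm)
library(GenomicRanges)
```

## The problem

Plant RNA polymerase V (Pol V) synthesizes the scaffold non-coding RNAs
that recruit the RNA-directed DNA methylation (RdDM) machinery, so the
positions where Pol V stops transcribing delimit where DNA methylation is
laid down. Pol V terminates spontaneously when it transcribes across
A-rich template DNA: the accumulating rU:dA hybrid pairs are unstable, the
transcription bubble collapses, and the transcript is released. On the
non-template strand this termination signal reads as a run of Ts just
downstream of the transcript end site (TES), and as poly(U) at the 3' end
of the nascent RNA.

This package implements the sequence-level computations that detect and
quantify that signal — a windowed T-richness score, homopolymer run
statistics, termination-region classification, and strand-aware metagene
profiling — and a synthetic-genome generator that plants the signal at
known positions so every stage can be validated against ground truth.

## The richness score

For a genomic position $k$, the score is computed from the 7-bp window
$k-3..k+3$. With $t$ the number of matching bases (T for the T-score; A or
T for the AT-score), $x_i$ the length of the $i$-th run of consecutive
matches, and $g$ the longest run of consecutive non-matches:

$$\mathrm{Score}(k) = \max\!\left(t + \sum_i \frac{x_i (x_i - 1)}{2} - g,\; 0\right)$$

The bonus $\sum_{j=1}^{x-1} j = x(x-1)/2$ rewards consecutive matches (a
run of 7 scores $7 + 21 = 28$, the maximum for a 7-bp window), the penalty
$g$ suppresses windows dominated by a long non-match run, and the clamp
keeps the score nonnegative:

```{r}
score_window("TTTTTTT", scoring_config("T"))$score
score_window("TTCCTTT", scoring_config("T"))$score   # runs 2+3: 5 + (1+3) - 2
score_window("CCTCCCC", scoring_config("T"))$score   # 1 + 0 - 4, clamped
score_window("ATATATA", scoring_config(c("A","T")))$score
```

Strand handling: the reverse-strand score of a position is the score of
the reverse-complemented window. Because $t$, the run multiset and $g$ are
invariant under reversing the window, this is computed by matching the
complemented base set on the forward sequence — so the reverse-strand
T-score track equals the forward-strand A-score track, a property the test
suite asserts position-wise. A transcript's non-template strand is its own
strand, so "non-template T-score" means the strand-matched track at its
TES.

Numerical choices worth stating:

* **N bases** never match and count toward the non-match run $g$, a
  conservative rule for ambiguous sequence.
* **Chromosome ends**: positions within 3 bp of an end are not scored
  (reported as `NA`), rather than scored on truncated windows — truncation
  would change the score's range. `NA` is distinct from a score of 0,
  which is meaningful, and `NA` positions are excluded from metagene
  means rather than zero-filled.
* The production scorer is a vectorized streaming implementation (rolling
  sums over incrementally extended run indicators); `score_window()` is
  the direct transcription of the formula. The suite compares them on all
  $4^7 = 16384$ windows and on random genomes, both strands, both modes.
* `scoring_config()` generalizes the match set and half-width, but the
  defaults (`match = "T"`, `half_width = 3`) are the published statistic;
  nothing in the pipeline changes them.

## Termination regions and classification

Two transcript cohorts enter the classification: a NET-seq-like set whose
3' ends are nucleotide-precise, and a RIP-seq-like set whose assembled 3'
ends only approximate termination sites. After the abundance/length
filters (strictly TPM > 5 and length < 5000 bp for NET; TPM > 1 and
length < 5000 bp for RIP), the termination region of each RIP transcript
is the interval from 50 bp upstream to 200 bp downstream of its TES in
transcription direction (251 bp; clipped with a warning at chromosome
ends). A NET transcript is **terminal** when its TES falls inside any
same-strand region (boundaries included), otherwise **body** when its
interval is wholly contained in a same-strand RIP transcript, otherwise
**unassigned**. Terminal takes precedence over body, the labels partition
the input, and same-strand matching is required throughout because the
template/non-template logic is strand-specific. When a TES overlaps
several regions, the first in genome order is recorded as the match; the
label is unaffected.

The real analyses include a further category — 3' ends supported by raw
read signal but insufficient for assembly — that depends on read-level
evidence outside this package's inputs; those cases land in
`unassigned` here.

Coordinates are held in `GRanges` (1-based, closed), the standard
container in R genomics; BED and bedGraph files are converted at the
boundary by rtracklayer, so files on disk follow those formats' 0-based
half-open convention. Interval arithmetic was re-derived once in 1-based
terms and is pinned by hand-computed boundary tests (a plus-strand TES at
0-based position 1000 yields the 0-based half-open region [950, 1201)).

## Homopolymer tracks

For the 3'-end versus gene-body contrast, 40-bp windows are extracted on
the non-template strand — centered on the TES (covering TES−19..TES+20 in
transcription direction; the published description is "−20 to +20 nt",
and with an even width the extra base is placed downstream where the
signal lives) — and compared with randomly placed 40-bp windows inside
transcript bodies. The per-window statistic counts **non-overlapping**
occurrences of the ℓ-mer homopolymer, i.e. greedy disjoint matches,
equivalently $\sum_{\text{runs}} \lfloor x/\ell \rfloor$; frequency is
motif count divided by the number of windows. The phrase "non-overlapping
consecutive nucleotides counted" admits a second reading — maximal runs of
exactly length ℓ — which is available as `mode = "exact"`; greedy counting
is the default as the literal reading. Body windows exclude starts whose
window center lies within half a window of the TES (waived when the
transcript admits no other window); one window per transcript is drawn by
default, as the published text does not state a count.

Poly-tract anchoring for metagene analysis follows the repeat rules:
repeats longer than 2-mers (≥ 3) are recorded, and the anchor is the start
of the longest run of at least 6 (> 5-mer), ties resolved leftmost.

## Metagene profiling and the flank comparison

`extract_matrix()` builds an anchor × relative-position matrix oriented
along transcription (minus-strand rows are reversed), `metagene_profile()`
bins it into 5-bp bins, and `flank_test()` compares the 50-bp flanks
either side of the TES with a two-sided Welch two-sample t test. Design
choices:

* The anchor base itself belongs to neither flank — "upstream of the TES"
  versus "downstream of the TES" is otherwise ambiguous by one base.
* Each anchor contributes one number per side (its flank mean). Whether
  the published test pooled per-base values or per-anchor means is not
  stated; per-anchor means are the default because anchors, not bases,
  are the independent units. `pooled = TRUE` gives the alternative.
* If both flank vectors are constant and equal (a degenerate input where
  the t test is undefined), the comparison reports t = 0, p = 1.
* The per-transcript maximum-signal position resolves ties to the 3'-most
  position. This is conservative for the claim being tested in one sense —
  it never manufactures a 3' peak from a 5' one — but it does map uniform
  signal to the transcript end, so tie resolutions are counted and
  reported.

## The synthetic generator

`synth_generate()` emulates exactly the structure the analyses assume:

* i.i.d. background bases at a configurable GC content (default 0.36,
  Arabidopsis-like). There is no dinucleotide structure: the statistics
  under test depend only on run structure, and an i.i.d. null keeps the
  background T-run frequencies interpretable.
* 500 non-overlapping transcripts of 200–2000 bp packed with random
  300–800 bp gaps and 600-bp chromosome-end margins onto 2 × 1 Mb
  chromosomes, alternating strands so every orientation code path is
  exercised.
* A fraction (default 0.8) of transcripts receives a poly-T tract on the
  non-template strand, length 6–12 (the analysis scripts and acceptance
  checks fix length 8), starting 0–10 bp downstream of the TES. For a
  minus-strand transcript the mirrored poly-A is written on the forward
  strand.
* NET-seq-like signal: per-base counts are Poisson with mean
  $m q^{d}$ — $m = 50$ at the TES decaying geometrically ($q = 0.8$) with
  distance $d$ upstream — plus uniform body noise (mean 0.05/base). Two
  parameters suffice to reproduce the sharp 3'-end peak shape.
* `synth_net_rip()` derives the matched cohorts: the dataset transcripts
  are the NET set (precise ends), and the RIP set jitters each 3' end
  within transcription-direction offsets that keep the NET TES inside the
  RIP termination region, emulating approximate assembly while making
  every planted label `terminal`.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: read-level artifacts (PCR duplicates, mapping
bias, soft-clipping), transcript abundance structure beyond a lognormal
TPM, dinucleotide/isochore composition, overlapping or nested
transcription units, and genuine biological variation in tract position
and purity. Recovery results here validate the computations, not the
biology.

## Problem sizes and determinism

All simulations run at 2 × 1 Mb genomes with 500 transcripts — large
enough that flank tests operate at the cohort sizes the analyses use,
small enough that the whole suite and the analysis scripts run in
minutes. Every random step (genome, placement, TPM, signal, jitter, body
windows) flows from a single integer seed, and regeneration under the
same seed is byte-identical through file round-trips.

The null behaviour is part of the design: with `planted_fraction = 0` the
TES flank comparison must *not* reject (two-sided p approximately uniform
across seeds), and the test suite checks this across 20 seeds alongside
the positive recovery under planting.

## Known limitations

* Whether the original genome-wide tracks scored truncated windows at
  chromosome ends is unstated; the omission rule here is declared, not
  inferred.
* The published transcript counts (8197 NET transcripts, 2472 terminal,
  88.9% ChIP overlap) depend on deposited sequencing data and are not
  reproducible from sequence alone; this package reproduces the *pattern*
  (downstream T-score step-up, 3'-end poly-T enrichment, exact label
  recovery) on synthetic ground truth instead.
* bigWig output is not supported (bedGraph only), and BAM-level
  processing is out of scope: inputs are already per-base tracks and
  interval annotations.
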