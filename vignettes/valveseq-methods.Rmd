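---
title: "Measuring transcriptional valves by pooled direct RNA sequencing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring transcriptional valves by pooled direct RNA sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(valveseq)
```

## The measurement problem

A transcriptional valve is a two-part cassette — a tunable *modifier*
followed by an intrinsic *core terminator* — placed between transcription
units. The fraction of RNA polymerases that terminate at the valve, its
termination efficiency $T_e$, sets the ratio of the two transcript isoforms
(terminated versus read-through) and hence the relative expression of
downstream units, purely at the level of transcription.

Characterizing a combinatorial library of such valves (spacer x modifier x
terminator) is awkward with fluorescent reporters or short reads. Nanopore
direct RNA sequencing (dRNA-seq) reads whole transcripts, so every read
contains its design's own sequence — an *intrinsic barcode* — and a single
pooled run can be demultiplexed into per-design, nucleotide-resolution read
depth profiles. This package implements that computational pipeline
end-to-end, together with a read simulator that provides ground truth for
validating every stage.

## The estimator

For a design with reference coordinates $x_s$ (first base of the modifier,
or of the terminator when no modifier is present) and $x_e$ (first base
after the core terminator), and read depth profile $R(x)$ built from the
filtered, demultiplexed reads,

$$T_e = \frac{R(x_s) - R(x_e)}{R(x_s)}.$$

Profiles are reported normalized, $N(x) = R(x)/R(x_s)$, with the
per-nucleotide drop $\Delta(x) = N(x-1) - N(x)$. Because the drops
telescope, $\sum_{x \in (x_s,\,x_e]} \Delta(x) = T_e$ holds to machine
precision for every profile — the test suite asserts this identity, and it
is a useful internal consistency check on any profile manipulation.

Peaks of $\Delta$ within the valve are called as termination positions
(reported as the final transcribed base, with weights proportional to
their drops, secondary peaks kept at $\ge 25\%$ of the maximum by
default); the U-tract of a called position is quantified as the number of
U residues in the 8-nt window ending at that base (a window *excluding*
the final base is available as a flag).

## Coordinates

All coordinates are 1-based and inclusive, the R/Bioconductor convention
used by `IRanges` and friends; GFF3 output is therefore written without
any shifting. The valve end $x_e$ is defined as the first base *after* the
terminator, so terminated reads never contribute depth at $x_e$ and the
estimator above is exact on clean data. This definition coincides
numerically with a 0-based half-open terminator end, which makes the
arithmetic directly comparable with pipelines written in that convention.
A consequence of the definition is that the 3' fixed flank must be
nonempty for $T_e$ to be measurable.

## The read simulator

The simulator is the package's source of ground truth, and its defaults
are the study conditions used throughout the tests:

* **Isoforms.** Each read terminates with probability `true_te` at a
  position drawn from the design's termination-weight distribution
  (default: a single position at the middle of the terminator's 3' half,
  i.e. just past the hairpin within the U-tract), otherwise it spans the
  full reference. A 30-nt poly(A) tail is appended either way.
* **Errors.** Substitution-only, each base independently mutated to one of
  the other three with probability 0.15 by default — the error level
  typical of nanopore dRNA-seq basecalls. Insertions and deletions are not
  simulated; the affine-gap aligner is nevertheless exercised on gapped
  test cases directly.
* **Truncation.** Optionally (probability 0 by default) a read loses a 5'
  prefix of uniform-random length, keeping at least `min_kept_length`
  (30 nt); this is the forward model behind the deviation correction.
* **Reproducibility.** Every design draws from an RNG substream derived
  from the master seed and the design id, so pools are bit-identical under
  a fixed seed and per-design reads are invariant to library composition
  and iteration order.

What the simulator does *not* emulate — indels, homopolymer-specific
errors, quality scores, signal-level artifacts, 3'-end degradation —
bounds what passing tests can show: recovery results here demonstrate the
pipeline's correctness under its stated error model, not performance on
any particular flow cell.

## Demultiplexing

Reads are assigned by maximizing the raw local-alignment score against
every design reference (match +2, mismatch −3, gap of length $k$ costing
$5 + 2k$, seed word size 4 — a BLASTN-like parameterization suited to
high-error reads). Raw score replaces bitscore deliberately: at fixed
scoring parameters the bitscore is an increasing affine transform of raw
score, so rankings are identical and no Karlin–Altschul parameters are
needed. An e-value gate is likewise replaced by a raw `min_score`
threshold (default 30, roughly 15 matched bases). Reads with no hit at or
above threshold are excluded as `no_hit`; reads whose best score is shared
by two or more designs are excluded as `tie`, which makes assignment
invariant to design order and automatically censors reads that no longer
contain design-distinguishing sequence. Only the forward strand is scored
(dRNA-seq is strand-specific); reverse-strand scanning is available as a
flag on the padding filter but not on the aligner.

The implementation is a seed-and-extend aligner in C++: exact word seeds
are binned by diagonal, corroborated diagonals (at least 2 seeds and at
least 5% of the best diagonal's count on large problems; every seed
diagonal on problems up to 10,000 cells) are clustered and extended with a
banded affine DP (half-width 16). A full Smith–Waterman oracle
(`local_align_dp`) is part of the package surface; the seeded score can
never exceed it, and equals it on ≥95% of random seeded pairs — both
properties are under test, as is agreement of the oracle itself with
`Biostrings::pairwiseAlignment`. For pooled demultiplexing a long-word
(10-mer) diagonal screen shortlists 8 candidate designs per read — always
including every design tied at the screen maximum, so duplicated designs
still surface as ties — before full seeded scoring; agreement with
brute-force all-pairs DP assignment is ≥99% at 15% substitutions.

## Read filtering

Following demultiplexing, a read is discarded only when it *both* lacks
the full design cassette (within a 5-nt end slack) *and* its 3' end falls
between the spacer start and 20 nt into the core terminator. Reads in that
window are artifacts that can be confused with neither termination (which
produces ends deep in the terminator, past the hairpin) nor read-through;
the conjunction keeps both genuine isoform classes. The margin and slack
are configurable.

## The deviation correction

5'-truncated reads deplete coverage at $x_s$ relative to $x_e$ and bias
$T_e$ downward. The correction is a forward-simulation model: pools are
simulated on a calibration library across a grid of efficiencies (default
0 to 1 in steps of 0.05), pushed through the *complete* pipeline, and the
mean measured $T_e$ recorded; correction then inverts the measured-vs-true
map by monotone linear interpolation and clamps to $[0,1]$. Three design
choices matter:

* **Truth axis.** The map's truth axis is the *realized* terminated
  fraction of each calibration pool, not the nominal grid value, so the
  fitted deviation reflects pipeline distortion only and is exactly zero
  when distortion is absent.
* **Monotonization.** Finite calibration pools give grid means that are
  never exactly monotone, so by default the fit is passed through isotonic
  regression; `monotonize = FALSE` restores a hard error on non-monotone
  fits for users who prefer to be told.
* **Calibration library.** Calibration uses one design per terminator
  (`build_synthetic_library(1, 1, n)`): in libraries where designs share
  terminators, deeply truncated reads lose all distinguishing sequence and
  are censored as ties, which both shrinks and confounds the bias being
  calibrated. On such a library, with 20% truncation and 600 reads per
  design per grid point, corrected efficiencies retain less than a fifth
  of the raw absolute bias on independent pools (asserted in the test
  suite and recomputed by `scripts/acceptance.R`).

The raw efficiency is reported unclamped (slightly negative values are
diagnostic of distortion); only the corrected value is clamped.

## Arrays

For an array of transcription units separated by valves with efficiencies
$t_1, \dots, t_k$, the abundance of unit $i$ relative to unit 1 is
$\prod_{j<i}(1-t_j)$, and the terminated : read-through isoform ratio of a
single valve is $T_e : (1-T_e)$. The array module builds an annotated
array template, simulates polymerase traversal, and measures each valve
with the same `compute_te` used for single designs; a 3-unit array with
designed efficiencies (0.3, 0.6) recovers (1, 0.7, 0.28) within ±0.03
from 2,000 error-free reads.

## Generated sequence and its filters

Spacers are uniform-composition random DNA ending in the stop codon TAA
(a coding-region-like composition can be supplied as a preset). Padding
and modifier filler is rejection-sampled against three filters: no
homopolymer of length ≥4; no EcoRI (GAATTC), SpeI (ACTAGT) or AatII
(GACGTC) recognition site (given strand only by default, as the inserts
are directional); and no predicted hairpin under a deliberately
self-contained surrogate — two disjoint reverse-complementary segments of
≥4 nt separated by ≥3 nt. The surrogate replaces an external inverse
folding engine; it is conservative (palindromic 4-mers such as ACGT count
as stems) but deterministic, configurable, and testable. Synthetic core
terminators are idealized hairpins (GC-biased stem, loop, reverse
complement, U8 tract) used for simulation studies; real terminator
sequences enter through `part()`.

## Problem sizes

The shipped tests and the acceptance script run entirely on simulated
data at sizes chosen to make the Monte-Carlo assertions sharp on a single
CPU: 1183-design enumeration for the combinatorial count; 96 designs x 20
reads for error-free demultiplexing exactness; 50 designs x 500 reads at
15% substitutions for efficiency recovery (RMSE ≤ 0.05); 30 designs x 20
reads for brute-force-DP assignment agreement; 6-design calibration x 600
reads per grid point for the deviation correction; 2,000 reads for array
stoichiometry. The same code paths scale to the published library size —
`demultiplex_pool` is linear in reads x shortlist — but the shipped runs
are deliberately small enough to re-execute routinely.

## Known limitations

* The error model is substitution-only; gapped alignment is validated on
  synthetic gapped pairs rather than simulated indel reads.
* The hairpin surrogate is not a thermodynamic folding model and will both
  pass some structured sequences and reject some unstructured ones.
* The deviation model corrects the distortions present in its forward
  simulation (5' truncation); distortions outside the model — 3'
  degradation, coverage-dependent basecall quality, polymerase drop-off —
  are not corrected.
* Ties are excluded rather than probabilistically resolved; libraries with
  near-duplicate designs will lose a corresponding fraction of reads.
* Group-level metrics are descriptive; no hypothesis testing is performed.
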