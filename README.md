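# valveseq

Pooled characterization of **transcriptional valves** — modifier +
intrinsic-terminator cassettes that set the fraction of RNA polymerases
terminating versus reading through — from nanopore **direct RNA sequencing
(dRNA-seq)**. Because dRNA-seq reads whole transcripts, every read carries
its design's own sequence as an *intrinsic barcode*: an entire combinatorial
library (spacer × modifier × core terminator) can be assayed as one pooled
sample and demultiplexed computationally into per-design, nucleotide-
resolution read-depth profiles.

The package is aimed at synthetic biologists and sequencing bioinformaticians
who want to design such libraries, validate an analysis pipeline against
simulated ground truth, and measure termination efficiencies

> *T*<sub>e</sub> = [R(x<sub>s</sub>) − R(x<sub>e</sub>)] / R(x<sub>s</sub>)

where R(x) is read depth at reference position x, x<sub>s</sub> is the valve
start (first modifier base) and x<sub>e</sub> the first base after the core
terminator. Drops of the normalized profile telescope exactly to
*T*<sub>e</sub>, termination positions are called from the per-nucleotide
Δ profile, U-tracts are quantified in the 8 nt ending at each termination
point, and a forward-simulation deviation model corrects the bias introduced
by 5′-truncated reads. For valve-separated gRNA arrays, unit *i* is expressed
at relative abundance ∏<sub>j&lt;i</sub>(1 − *T*<sub>e,j</sub>).

What's inside:

* **Library design** — combinatorial enumeration with exact part intervals
  (FASTA + GFF3 I/O), spacer/padding generators with homopolymer,
  restriction-site (EcoRI/SpeI/AatII) and hairpin-surrogate filters, design
  frequencies predicted from part frequencies.
* **Read simulator** — terminated/read-through isoform mixtures with
  poly(A) tails, 15% substitution errors, optional 5′ truncation, per-design
  RNG substreams, FASTQ + ground-truth output.
* **Demultiplexer** — seed-and-extend affine-gap local aligner in C++
  (match +2, mismatch −3, gap 5+2k, word size 4) with a full Smith–Waterman
  oracle; best-score assignment with tie exclusion.
* **Profiles & measurement** — truncation filter, depth/normalized/Δ
  profiles, *T*<sub>e</sub>, termination-point calls, U-tract counts,
  deviation correction, isoform and array stoichiometry.
* **Metrics & simulation harness** — tuning/insulation metrics (percentage
  deviation, CV across spacers), replicate agreement, frequency-deviation
  reports, and a seeded simulation study of accuracy versus error rate.

## Worked example

Build a 12-design library, simulate an error-ridden pooled run, and measure
every valve:

```r
library(valveseq)

lib <- build_synthetic_library(n_spacers = 2, n_modifiers = 2,
                               n_terminators = 3, seed = 5)
set.seed(1)
true_te <- setNames(runif(length(lib$designs)), names(lib$designs))
models  <- Map(truth_model, lib$designs, true_te)
pool    <- simulate_pool(lib$designs, models,
                         sim_config(substitution_rate = 0.15,
                                    reads_per_design = 50, seed = 3))
res <- characterize_pool(pool, lib$designs)

assignment_accuracy(res$demux, pool$reads)
#> [1] 1
head(res$measurements[, c("design_id", "n_reads", "te_raw",
                          "dominant_position", "u_count")], 3)
#>   design_id n_reads    te_raw dominant_position u_count
#> 1  S1_M1_T1      48 0.2500000               123       1
#> 2  S1_M1_T2      50 0.2800000               123       1
#> 3  S1_M1_T3      49 0.5306122               123       0
sqrt(mean((res$measurements$te_raw - true_te[res$measurements$design_id])^2))
#> [1] 0.05062058
```

All 600 simulated reads (15% per-base substitutions) are assigned to their
design of origin; each design's raw *T*<sub>e</sub> is the fractional depth
drop across its valve and lands within binomial noise of the programmed
truth (RMSE ≈ 0.05 at 50 reads/design). `dominant_position` is the called
final transcribed base and `u_count` the number of U residues in the 8 nt
ending there — low here because the simulator's default termination point
sits at the hairpin–U-tract junction, so the window is stem-dominated;
supply explicit `termination_weights` inside the U-tract for realistic
U-rich windows. The numbered scripts under `analysis/` run the same workflow
end to end — library design, simulation, demultiplexing, profiling,
deviation correction, array stoichiometry, and an error-rate study — and
write their tables under `results/`.

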