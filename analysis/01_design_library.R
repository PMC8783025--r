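#!/usr/bin/env Rscript
# Step 1 — combinatorial library design.
#
# Builds the full transcriptional-valve library from generated parts at the
# published scale (7 spacers x 13 modifiers x 13 core terminators = 1183
# designs), writes the reference FASTA + GFF3 annotation, and a smaller
# 96-design working library used by the later steps. Also predicts design
# frequencies from (here, uniform) part frequencies.

suppressPackageStartupMessages(library(valveseq))
dir.create("results", showWarnings = FALSE)
seed <- 20260927

parts <- c(
  lapply(1:7, function(i) generate_spacer(33, seed = seed + i, id = paste0("s", i))),
  lapply(1:13, function(i) part(paste0("m", i), "modifier",
                                generate_padding(24, seed = seed + 100 + i))),
  lapply(1:13, function(i) generate_terminator(seed = seed + 200 + i,
                                               id = paste0("t", i)))
)
full <- enumerate_designs(part_set(parts),
                          flank5 = generate_padding(40, seed = seed + 301),
                          flank3 = generate_padding(60, seed = seed + 302))
cat("Full library:", length(full), "designs (7 x 13 x 13 = 1183)\n")

pf <- list(spacer = setNames(rep(1 / 7, 7), paste0("s", 1:7)),
           modifier = setNames(rep(1 / 13, 13), paste0("m", 1:13)),
           terminator = setNames(rep(1 / 13, 13), paste0("t", 1:13)))
freq <- predict_design_frequencies(pf, full)
cat("Predicted frequencies sum to", sum(freq),
    "- uniform parts give each design", signif(freq[1], 3), "\n")
write_tsv_table(data.frame(design_id = names(freq),
                           predicted_frequency = unname(freq)),
                "results/predicted_frequencies.tsv")

# working library for the simulation-based steps
lib <- build_synthetic_library(4, 4, 6, seed = seed)
write_designs(lib$designs, "results/designs.fa", "results/designs.gff3")
write_tsv_table(design_table(lib$designs), "results/design_table.tsv")
cat("Working library:", length(lib$designs),
    "designs written to results/designs.fa + results/designs.gff3\n")
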