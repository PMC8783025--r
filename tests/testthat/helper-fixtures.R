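# shared fixtures, built in code at test time

tiny_parts <- function() {
  part_set(list(
    part("S1", "spacer", "ATGACCGTTGCAATTCACCGGTTAGCCAGATAA"),
    part("S2", "spacer", "ATGGTCAAGCCTCTAGATCACGGAGACTGGTAA"),
    part("M1", "modifier", "CAGTCCATAGGTCACTTGACCGGA"),
    part("M2", "modifier", "TGCATCGGATCTGAGTCCTAGCAT"),
    part("T1", "terminator", "GGCACGCCGCTAATGCGAGCGGCGTGCCTTTTTTTT"),
    part("T2", "terminator", "CCGAGGCTGCAATCATTGCAGCCTCGGTTTTTTTTT"),
    part("T3", "terminator", "GCGCCTACCGTTAGATACGGTAGGCGCTTTTTTTTT")
  ))
}

tiny_designs <- function(flank5 = "ACCATTGACGGCATCAGTCAGGACATTGCCATCGAGGGAC",
                         flank3 = paste0("CAGGATTCGCCATGTCAAGGCATTCCGACTGGAC",
                                         "ATCCATGGCAGTCATCGGAGCATCAG")) {
  enumerate_designs(tiny_parts(), flank5 = flank5, flank3 = flank3)
}

# simulate + characterize in one step
quick_run <- function(designs, te, config, scoring = scoring_scheme(), ...) {
  models <- Map(truth_model, designs, te[names(designs)])
  pool <- simulate_pool(designs, models, config)
  list(pool = pool,
       result = characterize_pool(pool, designs, scoring = scoring, ...))
}

# per-design terminated fraction among a pool's reads
terminated_fraction <- function(pool) {
  tapply(pool$reads$is_terminated, pool$reads$design_id, mean)
}

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
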