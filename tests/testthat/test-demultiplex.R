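test_that("full-DP local alignment matches hand-computed scores", {
  expect_identical(local_align_dp("ACGTTACGTT", "ACGTTACGTT")$score, 20L)

  # one internal mismatch: 9 matches * 2 - 3 beats any trimmed segment
  expect_identical(local_align_dp("ACGTACGTAC", "ACGTTCGTAC")$score, 15L)

  # 1-nt insertion: the optimal LOCAL alignment is the exact 5-mer TACGT
  # (score 10), not the full-length gapped alignment (16 - 7 = 9)
  h <- local_align_dp("ACGTACGT", "ACGTTACGT")
  expect_identical(h$score, 10L)

  # a pair where the gapped path is genuinely optimal:
  # 20 matches minus one length-1 gap = 40 - 7 = 33
  x <- "ACGGATCCTGTTAGCAGCAT"
  y <- paste0(substr(x, 1, 10), "T", substr(x, 11, 20))
  expect_identical(local_align_dp(x, y)$score, 33L)

  expect_error(local_align_dp("", "ACGT"), "empty")
})

test_that("full-DP scores agree with an independent aligner on random pairs", {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                                  baseOnly = TRUE)
  set.seed(31)
  for (i in 1:60) {
    a <- random_dna_str(sample(8:60, 1))
    b <- random_dna_str(sample(8:60, 1))
    ours <- local_align_dp(a, b)$score
    ref <- Biostrings::pairwiseAlignment(a, b, type = "local",
                                         substitutionMatrix = mat,
                                         gapOpening = 5, gapExtension = 2)
    expect_identical(ours, max(0L, as.integer(Biostrings::score(ref))))
    # symmetry under swap
    expect_identical(ours, local_align_dp(b, a)$score)
  }
})

test_that("seeded alignment is bounded by and usually equals the DP oracle", {
  sc <- scoring_scheme(min_score = 1)

  # identical 60-mers: single hit, perfect score, equal to oracle
  s <- random_dna_str(60)
  hits <- seeded_align(s, s, sc)
  expect_identical(hits$score[1], 120L)
  expect_identical(local_align_dp(s, s, sc)$score, 120L)

  # disjoint 4-mer vocabularies: no seeds, no hits
  expect_identical(nrow(seeded_align(strrep("AC", 20), strrep("GT", 20), sc)), 0L)

  set.seed(17)
  equal <- 0
  for (i in 1:60) {
    core <- random_dna_str(8)
    a <- paste0(random_dna_str(sample(0:26, 1)), core,
                random_dna_str(sample(0:26, 1)))
    b <- paste0(random_dna_str(sample(0:26, 1)), core,
                random_dna_str(sample(0:26, 1)))
    dp <- local_align_dp(a, b, sc)$score
    hs <- seeded_align(a, b, sc)
    top <- if (nrow(hs)) hs$score[1] else 0L
    expect_lte(top, dp)
    if (top == dp) equal <- equal + 1
  }
  expect_gte(equal / 60, 0.95)
})

test_that("reads are assigned to the best design, with ties excluded", {
  designs <- tiny_designs()
  seqs <- setNames(vapply(designs, `[[`, character(1), "sequence"),
                   names(designs))

  # error-free read from a known design
  read <- paste0(seqs[["S1_M2_T3"]], strrep("A", 30))
  a <- assign_read(read, seqs)
  expect_identical(a$status, "assigned")
  expect_identical(a$design_id, "S1_M2_T3")

  # duplicated design: identical top scores must be excluded as a tie
  dup <- c(seqs, setNames(seqs[["S1_M2_T3"]], "DUP"))
  a2 <- assign_read(read, dup)
  expect_identical(a2$status, "unassigned_tie")
  expect_true(is.na(a2$design_id))

  # order invariance
  a3 <- assign_read(read, rev(seqs))
  expect_identical(a3$design_id, a$design_id)
  expect_identical(a3$score, a$score)

  # garbage read: no hit above the score threshold
  a4 <- assign_read(strrep("A", 40), seqs)
  expect_identical(a4$status, "unassigned_no_hit")
})

test_that("pooled demultiplexing is exact on error-free pools", {
  designs <- tiny_designs()
  te <- setNames(rep(0.5, length(designs)), names(designs))
  run <- quick_run(designs, te,
                   sim_config(substitution_rate = 0, reads_per_design = 10,
                              seed = 21))
  dmx <- run$result$demux
  expect_identical(dmx$summary$n_assigned, nrow(run$pool$reads))
  expect_identical(assignment_accuracy(dmx, run$pool$reads), 1)

  # empty input
  empty <- demultiplex_pool(character(0), designs)
  expect_identical(nrow(empty$assignments), 0L)
  expect_identical(empty$summary$n_assigned, 0L)
})

test_that("seeded pooled assignment agrees with brute-force DP assignment", {
  lib <- build_synthetic_library(2, 3, 5, seed = 13)
  designs <- lib$designs
  seqs <- setNames(vapply(designs, `[[`, character(1), "sequence"),
                   names(designs))
  te <- setNames(rep(0.5, length(designs)), names(designs))
  run <- quick_run(designs, te,
                   sim_config(substitution_rate = 0.15, reads_per_design = 20,
                              seed = 23))
  a <- run$result$demux$assignments

  agree <- 0; compared <- 0
  for (i in seq_len(nrow(a))) {
    scores <- vapply(seqs, function(r)
      local_align_dp(run$pool$reads$sequence[i], r)$score, numeric(1))
    tie <- sum(scores == max(scores)) > 1
    if (tie || max(scores) < 30 || a$status[i] != "assigned") next
    compared <- compared + 1
    agree <- agree + (a$design_id[i] == names(which.max(scores)))
  }
  expect_gt(compared, 0.9 * nrow(a))
  expect_gte(agree / compared, 0.99)
})

test_that("assignment accuracy degrades monotonically with error rate", {
  designs <- tiny_designs()
  te <- setNames(rep(0.5, length(designs)), names(designs))
  acc <- vapply(c(0, 0.05, 0.15, 0.25), function(rate) {
    run <- quick_run(designs, te,
                     sim_config(substitution_rate = rate,
                                reads_per_design = 30, seed = 29))
    assignment_accuracy(run$result$demux, run$pool$reads)
  }, numeric(1))
  expect_identical(acc[1], 1)
  # non-increasing up to Monte-Carlo jitter at this pool size
  expect_true(all(diff(acc) <= 0.01))
})
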