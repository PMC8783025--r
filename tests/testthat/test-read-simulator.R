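test_that("transcript simulation honours degenerate efficiencies", {
  d <- tiny_designs()[[1]]
  pos <- d$terminator_start + 25L

  set.seed(1)
  m1 <- truth_model(d, 1, setNames(1, pos), polyA_length = 10)
  for (i in 1:20) {
    r <- simulate_transcript(d, m1)
    expect_true(r$is_terminated)
    expect_identical(r$termination_position, pos)
    expect_identical(r$sequence,
                     paste0(substr(d$sequence, 1, pos), strrep("A", 10)))
  }

  m0 <- truth_model(d, 0, polyA_length = 10)
  for (i in 1:20) {
    r <- simulate_transcript(d, m0)
    expect_false(r$is_terminated)
    expect_identical(r$sequence, paste0(d$sequence, strrep("A", 10)))
  }

  expect_error(truth_model(d, 1.2), "\\[0, 1\\]")
  expect_error(truth_model(d, 0.5, setNames(1, d$x_e + 10L)), "terminator interval")
  expect_error(truth_model(d, 0.5, setNames(c(0.5, 0.4),
                                            c(pos, pos + 1L))), "sum to 1")
})

test_that("terminated counts follow the binomial at fixed seed", {
  d <- tiny_designs()[[1]]
  m <- truth_model(d, 0.8)
  set.seed(42)
  n <- 1000
  terminated <- sum(vapply(seq_len(n),
                           function(i) simulate_transcript(d, m)$is_terminated,
                           logical(1)))
  expect_lt(abs(terminated - 800), 3 * sqrt(1000 * 0.8 * 0.2))
})

test_that("substitutions hit at the configured rate and preserve length", {
  s <- random_dna_str(200)
  expect_identical(apply_substitutions(s, 0), s)

  set.seed(9)
  s1 <- apply_substitutions(s, 1)
  expect_identical(nchar(s1), nchar(s))
  expect_true(all(strsplit(s1, "")[[1]] != strsplit(s, "")[[1]]))

  set.seed(10)
  long <- random_dna_str(10000)
  mut <- apply_substitutions(long, 0.15)
  hamming <- sum(strsplit(long, "")[[1]] != strsplit(mut, "")[[1]])
  expect_lt(abs(hamming - 1500), 3 * sqrt(10000 * 0.15 * 0.85))
  expect_error(apply_substitutions(s, 1.5), "\\[0, 1\\]")
})

test_that("truncation removes only 5' prefixes at the configured rate", {
  d <- tiny_designs()[[1]]
  r0 <- list(sequence = paste0(d$sequence, strrep("A", 30)),
             is_terminated = FALSE, termination_position = NA_integer_,
             truncation_position = NA_integer_)
  expect_identical(apply_truncation(r0, 0), r0)
  # no legal cut when the whole read must be kept
  expect_identical(apply_truncation(r0, 1, min_kept = nchar(r0$sequence)), r0)

  set.seed(11)
  n <- 10000
  len <- nchar(r0$sequence)
  cuts <- vapply(seq_len(n), function(i) {
    r <- apply_truncation(r0, 0.5, min_kept = 30)
    if (is.na(r$truncation_position)) {
      expect_identical(r$sequence, r0$sequence)
      0L
    } else {
      # 3' end unchanged, prefix removed
      expect_identical(r$sequence,
                       substr(r0$sequence, r$truncation_position + 1, len))
      r$truncation_position
    }
  }, integer(1))
  expect_lt(abs(sum(cuts > 0) - n / 2), 3 * sqrt(n * 0.25))
  expect_true(all(cuts <= len - 30))
})

test_that("pool simulation is deterministic and design-order independent", {
  designs <- tiny_designs()[1:3]
  te <- setNames(c(0.2, 0.5, 0.9), names(designs))
  models <- Map(truth_model, designs, te)
  cfg <- sim_config(substitution_rate = 0.1, reads_per_design = 10, seed = 5)

  p1 <- simulate_pool(designs, models, cfg)
  p2 <- simulate_pool(designs, models, cfg)
  expect_identical(p1$reads, p2$reads)
  expect_identical(nrow(p1$reads), 30L)

  p_rev <- simulate_pool(rev(designs), rev(models), cfg)
  for (id in names(designs)) {
    a <- p1$reads[p1$reads$design_id == id, ]
    b <- p_rev$reads[p_rev$reads$design_id == id, ]
    rownames(a) <- rownames(b) <- NULL
    expect_identical(a, b)
  }

  expect_error(simulate_pool(designs, models[1:2], cfg), "missing truth model")
})

test_that("pools round-trip through FASTQ and the truth table", {
  designs <- tiny_designs()[1:2]
  models <- Map(truth_model, designs, c(0.4, 0.6))
  pool <- simulate_pool(designs, models,
                        sim_config(substitution_rate = 0, reads_per_design = 10,
                                   seed = 2))
  fq <- tempfile(fileext = ".fastq"); tt <- tempfile(fileext = ".tsv")
  write_pool(pool, fq, tt)

  back <- read_fastq_sequences(fq)
  expect_identical(unname(back), pool$reads$sequence)
  expect_identical(names(back), pool$reads$read_id)

  truth <- read.delim(tt)
  expect_identical(truth$read_id, pool$reads$read_id)
  expect_identical(truth$is_terminated, pool$reads$is_terminated)

  # byte-identical FASTQ on re-simulation
  pool2 <- simulate_pool(designs, models,
                         sim_config(substitution_rate = 0, reads_per_design = 10,
                                    seed = 2))
  fq2 <- tempfile(fileext = ".fastq")
  write_pool(pool2, fq2, tempfile())
  expect_identical(readLines(fq), readLines(fq2))
})

test_that("part-frequency mode allocates reads multinomially", {
  designs <- tiny_designs()
  models <- Map(truth_model, designs, rep(0.5, length(designs)))
  pf <- list(spacer = c(S1 = 0.5, S2 = 0.5),
             modifier = c(M1 = 0.9, M2 = 0.1),
             terminator = c(T1 = 1 / 3, T2 = 1 / 3, T3 = 1 / 3))
  cfg <- sim_config(substitution_rate = 0, reads_per_design = 50, seed = 3,
                    design_frequency_mode = "from_part_freqs", part_freqs = pf)
  pool <- simulate_pool(designs, models, cfg)
  expect_identical(nrow(pool$reads), 50L * length(designs))
  counts <- table(pool$reads$design_id)
  m1 <- sum(counts[grepl("_M1_", names(counts))])
  expect_lt(abs(m1 / sum(counts) - 0.9), 3 * sqrt(0.09 / sum(counts)))
})
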