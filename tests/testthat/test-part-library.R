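test_that("enumeration yields the full Cartesian product with exact intervals", {
  designs <- tiny_designs()
  expect_length(designs, 2 * 2 * 3)

  # brute-force count check over several role-count combinations
  for (cnt in list(c(1, 1, 1), c(2, 3, 4), c(0, 2, 2), c(3, 0, 2))) {
    parts <- c(
      lapply(seq_len(cnt[1]), function(i) generate_spacer(33, seed = i, id = paste0("s", i))),
      lapply(seq_len(cnt[2]), function(i) part(paste0("m", i), "modifier", generate_padding(20, seed = i))),
      lapply(seq_len(cnt[3]), function(i) generate_terminator(seed = i, id = paste0("t", i)))
    )
    ds <- enumerate_designs(part_set(parts))
    expect_length(ds, prod(pmax(cnt, 1)))
    expect_false(anyDuplicated(names(ds)) > 0)
  }

  # every part sits at its recorded interval (substring equality)
  ps <- tiny_parts()
  all_parts <- c(ps$spacer, ps$modifier, ps$terminator)
  seq_of <- setNames(vapply(all_parts, `[[`, character(1), "sequence"),
                     vapply(all_parts, `[[`, character(1), "id"))
  for (d in designs) {
    for (i in seq_len(nrow(d$intervals))) {
      iv <- d$intervals[i, ]
      expect_identical(substr(d$sequence, iv$start, iv$end),
                       unname(seq_of[iv$part_id]))
    }
    expect_identical(d$x_s, d$intervals$start[d$intervals$role == "modifier"])
    expect_identical(d$x_e, d$intervals$end[d$intervals$role == "terminator"] + 1L)
  }
})

test_that("enumeration fails without terminators and matches published scale", {
  expect_error(part_set(list(part("S1", "spacer", "ATGTAA"))), "no terminators")

  parts <- c(
    lapply(1:7, function(i) generate_spacer(33, seed = i, id = paste0("s", i))),
    lapply(1:13, function(i) part(paste0("m", i), "modifier", generate_padding(24, seed = 100 + i))),
    lapply(1:13, function(i) generate_terminator(seed = i, id = paste0("t", i)))
  )
  designs <- enumerate_designs(part_set(parts))
  expect_length(designs, 1183)
})

test_that("spacer generator is deterministic, TAA-terminated, on-composition", {
  s1 <- generate_spacer(33, seed = 1)
  s2 <- generate_spacer(33, seed = 1)
  expect_identical(s1$sequence, s2$sequence)
  expect_identical(nchar(s1$sequence), 33L)
  expect_identical(substr(s1$sequence, 31, 33), "TAA")
  expect_error(generate_spacer(2, seed = 1), ">= 3")

  # law of large numbers on the non-forced positions
  draws <- vapply(seq_len(10000), function(i)
    substr(generate_spacer(33, seed = i)$sequence, 1, 30), character(1))
  bases <- strsplit(paste(draws, collapse = ""), "")[[1]]
  freqs <- table(factor(bases, levels = c("A", "C", "G", "T"))) / length(bases)
  expect_true(all(abs(freqs - 0.25) < 0.02))
})

test_that("padding filters reject homopolymers, restriction sites and hairpins", {
  expect_false(passes_padding_filters("ACGTTTTACG")$pass)
  expect_identical(passes_padding_filters("ACGTTTTACG")$reasons, "homopolymer")
  expect_false(passes_padding_filters("ACGAATTCGT")$pass)
  expect_identical(passes_padding_filters("ACGAATTCGT")$reasons, "restriction site")
  # SpeI and AatII sites
  expect_false(passes_padding_filters("CGACTAGTCG")$pass)
  expect_false(passes_padding_filters("CGGACGTCCG")$pass)
  # GCAT arms: reverse complement ATGC occurs 3 nt downstream
  h <- passes_padding_filters("GCATTCAATGC")
  expect_false(h$pass)
  expect_identical(h$reasons, "hairpin")
  # stem-free, run-free, site-free sequence passes
  expect_true(passes_padding_filters("AACCAGACCA")$pass)
  # single base trivially passes
  expect_true(passes_padding_filters("A")$pass)
  expect_error(passes_padding_filters("ACGU"), "non-DNA")
})

test_that("padding generator is reproducible and respects its filters", {
  p1 <- generate_padding(20, seed = 7)
  p2 <- generate_padding(20, seed = 7)
  expect_identical(p1, p2)
  expect_identical(nchar(p1), 20L)
  expect_true(passes_padding_filters(p1)$pass)
  expect_identical(nchar(generate_padding(1, seed = 3)), 1L)
  expect_error(generate_padding(20, seed = 1, max_attempts = 0), "attempts")
})

test_that("predicted design frequencies are products and sum to one", {
  parts <- part_set(list(
    part("a1", "modifier", "CAGTCCAT"), part("a2", "modifier", "TGCATCGG"),
    part("b1", "terminator", "GGCACGCC"), part("b2", "terminator", "CCGAGGCT")
  ))
  designs <- enumerate_designs(parts)
  pf <- list(modifier = c(a1 = 0.6, a2 = 0.4),
             terminator = c(b1 = 0.9, b2 = 0.1))
  f <- predict_design_frequencies(pf, designs)
  # brute force over all four combinations
  expect_equal(sort(unname(f)), sort(c(0.54, 0.06, 0.36, 0.04)))
  expect_equal(sum(f), 1, tolerance = 1e-12)

  # invariant to design ordering
  f_rev <- predict_design_frequencies(pf, rev(designs))
  expect_equal(f[names(f_rev)], f_rev)

  # 0.75 / 0.25 terminator split with a single modifier
  parts2 <- part_set(list(part("a1", "modifier", "CAGTCCAT"),
                          part("b1", "terminator", "GGCACGCC"),
                          part("b2", "terminator", "CCGAGGCT")))
  d2 <- enumerate_designs(parts2)
  f2 <- predict_design_frequencies(
    list(modifier = c(a1 = 1), terminator = c(b1 = 0.75, b2 = 0.25)), d2)
  expect_equal(sort(unname(f2)), c(0.25, 0.75))

  expect_error(predict_design_frequencies(
    list(modifier = c(a1 = 1), terminator = c(b1 = 1)), designs), "missing")
  expect_error(predict_design_frequencies(
    list(modifier = c(a1 = 0.7, a2 = 0.4),
         terminator = c(b1 = 0.9, b2 = 0.1)), designs), "sum to 1")
})

test_that("designs round-trip through FASTA + GFF3", {
  designs <- tiny_designs()
  fa <- tempfile(fileext = ".fa"); gff <- tempfile(fileext = ".gff3")
  write_designs(designs, fa, gff)
  back <- read_designs(fa, gff)
  expect_identical(names(back), names(designs))
  for (id in names(designs)) {
    expect_identical(back[[id]]$sequence, designs[[id]]$sequence)
    expect_identical(back[[id]]$x_s, designs[[id]]$x_s)
    expect_identical(back[[id]]$x_e, designs[[id]]$x_e)
    expect_identical(back[[id]]$terminator_start, designs[[id]]$terminator_start)
  }
  ps <- tiny_parts()
  pfa <- tempfile(fileext = ".fa")
  write_parts_fasta(ps, pfa)
  back_ps <- read_parts_fasta(pfa)
  expect_identical(vapply(back_ps$terminator, `[[`, character(1), "sequence"),
                   vapply(ps$terminator, `[[`, character(1), "sequence"))
})
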