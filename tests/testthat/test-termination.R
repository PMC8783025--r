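test_that("termination efficiency is the fractional depth drop", {
  depth <- c(rep(100L, 30), rep(50L, 30))
  expect_identical(compute_te(depth, 10, 40), 0.5)
  expect_identical(compute_te(depth, 5, 25), 0)
  expect_error(compute_te(rep(0L, 10), 2, 8), "zero depth")
  expect_error(compute_te(depth, 40, 10), "x_s < x_e")
})

test_that("efficiency estimates are exact on error-free pools", {
  designs <- tiny_designs()[1:4]
  te <- setNames(c(0.15, 0.4, 0.75, 0.95), names(designs))
  run <- quick_run(designs, te, sim_config(substitution_rate = 0,
                                           reads_per_design = 60, seed = 47))
  frac <- terminated_fraction(run$pool)
  m <- run$result$measurements
  expect_equal(m$te_raw, as.numeric(frac[m$design_id]), tolerance = 1e-12)

  # across seeds the estimate concentrates at the binomial rate
  d <- designs[[1]]
  err <- vapply(1:30, function(s) {
    mods <- list(truth_model(d, 0.8)); names(mods) <- d$id
    pool <- simulate_pool(list(d), mods,
                          sim_config(substitution_rate = 0,
                                     reads_per_design = 500, seed = 1000 + s))
    res <- characterize_pool(pool, setNames(list(d), d$id))
    res$measurements$te_raw - 0.8
  }, numeric(1))
  se <- sqrt(0.8 * 0.2 / 500)
  expect_lte(sqrt(mean(err^2)), 1.2 * se)
})

test_that("termination points are called with renormalized drop weights", {
  # single step
  drop <- rep(0, 60); drop[35] <- 0.6
  cl <- call_termination_points(drop, 20, 50)
  expect_identical(cl$points$position, 34L)
  expect_identical(cl$points$weight, 1)
  expect_identical(cl$dominant, 34L)
  expect_identical(cl$max_drop, 0.6)

  # two equal steps: 0.5/0.5, dominant is 5'-most
  drop2 <- rep(0, 60); drop2[c(30, 40)] <- 0.25
  cl2 <- call_termination_points(drop2, 20, 50)
  expect_equal(cl2$points$weight, c(0.5, 0.5))
  expect_identical(cl2$dominant, 29L)

  # below-threshold secondary peaks are dropped
  drop3 <- rep(0, 60); drop3[30] <- 0.5; drop3[40] <- 0.1
  cl3 <- call_termination_points(drop3, 20, 50, secondary_fraction = 0.25)
  expect_identical(cl3$points$position, 29L)

  # no positive drop in the valve
  cl4 <- call_termination_points(rep(0, 60), 20, 50)
  expect_identical(nrow(cl4$points), 0L)
  expect_true(is.na(cl4$dominant))
})

test_that("bimodal termination weights are recovered from simulated pools", {
  d <- tiny_designs()[[1]]
  p1 <- d$terminator_start + 22L
  p2 <- d$terminator_start + 30L
  w <- setNames(c(0.7, 0.3), c(p1, p2))
  models <- list(truth_model(d, 0.9, w)); names(models) <- d$id
  pool <- simulate_pool(list(d), models,
                        sim_config(substitution_rate = 0,
                                   reads_per_design = 2000, seed = 53))
  res <- characterize_pool(pool, setNames(list(d), d$id))
  nd <- normalize_and_delta(res$profiles[[d$id]], d$x_s)
  cl <- call_termination_points(nd$drop, d$x_s, d$x_e)
  expect_setequal(cl$points$position, c(p1, p2))
  expect_equal(cl$points$weight[match(c(p1, p2), cl$points$position)],
               c(0.7, 0.3), tolerance = 0.05)
  expect_identical(cl$dominant, p1)
})

test_that("U-tract counting uses the 8-nt window ending at termination", {
  ref <- paste0(strrep("G", 20), "TTTTTTTT", "GCTTCTTT", strrep("C", 10))
  expect_identical(count_u_tract(ref, 28L), 8L)  # pure U-tract window
  expect_identical(count_u_tract(ref, 36L), 5L)  # GCTTCTTT
  expect_identical(count_u_tract(strrep("G", 30), 20L), 0L)
  expect_error(count_u_tract(ref, 7L), ">= 8")
  # invariant to sequence outside the window
  ref2 <- paste0(strrep("A", 20), "TTTTTTTT", "GCTTCTTT", strrep("T", 10))
  expect_identical(count_u_tract(ref2, 36L), count_u_tract(ref, 36L))
  # exclusive-of-final-base mode shifts the window by one
  expect_identical(count_u_tract(paste0(strrep("T", 8), "G", "C"), 9L,
                                 include_final = FALSE), 8L)
})

test_that("isoform and array stoichiometries follow the product rule", {
  expect_identical(isoform_stoichiometry(0.5), 1)
  expect_identical(isoform_stoichiometry(0), 0)
  expect_equal(isoform_stoichiometry(11 / 12), 11)
  expect_error(isoform_stoichiometry(1), "read-through")

  expect_identical(array_stoichiometry(c(0, 0)), c(1, 1, 1))
  expect_identical(array_stoichiometry(c(0.5, 0.5)), c(1, 0.5, 0.25))
  expect_error(array_stoichiometry(c(0.5, 1.2)), "\\[0, 1\\]")
  # non-increasing for any valid efficiencies
  set.seed(59)
  for (i in 1:20) {
    ab <- array_stoichiometry(runif(4))
    expect_true(all(diff(ab) <= 0))
  }
})

test_that("valve measurements integrate profile, calls and U-tract", {
  d <- tiny_designs()[[1]]
  p <- d$terminator_start + 25L
  models <- list(truth_model(d, 0.6, setNames(1, p))); names(models) <- d$id
  pool <- simulate_pool(list(d), models,
                        sim_config(substitution_rate = 0,
                                   reads_per_design = 200, seed = 61))
  res <- characterize_pool(pool, setNames(list(d), d$id))
  m <- res$measurements
  frac <- as.numeric(terminated_fraction(pool))
  expect_equal(m$te_raw, frac, tolerance = 1e-12)
  expect_identical(m$dominant_position, p)
  expect_identical(m$u_count, count_u_tract(d$sequence, p))
  expect_identical(m$depth_xs, 200L)
  expect_equal(m$max_drop, frac, tolerance = 1e-12)
})
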