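#' Build a synthetic combinatorial valve library
#'
#' Assembles a library from generated parts: random coding-like spacers,
#' filtered padding modifiers, and synthetic hairpin terminators, flanked
#' by fixed padding sequences for alignment context.
#'
#' @param n_spacers,n_modifiers,n_terminators part counts per role.
#' @param seed integer seed (part sequences are deterministic given it).
#' @param spacer_length,modifier_length part lengths in nt.
#' @param flank5_length,flank3_length fixed flank lengths in nt.
#' @return List with `parts` (a `part_set`), `designs` (named list of
#'   `valve_design`), `flank5`, `flank3`.
#' @export
build_synthetic_library <- function(n_spacers = 4, n_modifiers = 4,
                                    n_terminators = 6, seed = 1,
                                    spacer_length = 33, modifier_length = 24,
                                    flank5_length = 40, flank3_length = 60) {
  spacers <- lapply(seq_len(n_spacers), function(i)
    generate_spacer(spacer_length, seed = substream_seed(seed, paste0("S", i)),
                    id = paste0("S", i)))
  modifiers <- lapply(seq_len(n_modifiers), function(i)
    part(paste0("M", i), "modifier",
         generate_padding(modifier_length,
                          seed = substream_seed(seed, paste0("M", i)))))
  terminators <- lapply(seq_len(n_terminators), function(i)
    generate_terminator(seed = substream_seed(seed, paste0("T", i)),
                        id = paste0("T", i)))
  parts <- part_set(c(spacers, modifiers, terminators))
  flank5 <- generate_padding(flank5_length, seed = substream_seed(seed, "F5"))
  flank3 <- generate_padding(flank3_length, seed = substream_seed(seed, "F3"))
  list(parts = parts,
       designs = enumerate_designs(parts, flank5 = flank5, flank3 = flank3),
       flank5 = flank5, flank3 = flank3)
}

#' Simulation study of demultiplexing and efficiency recovery
#'
#' Builds a synthetic library, assigns every design a random true
#' termination efficiency, and for each substitution rate simulates a
#' pooled run, demultiplexes it, and measures the valves. Reports per-rate
#' assignment accuracy, efficiency-recovery error, and accuracy as a
#' function of each design's terminator distinctness (minimum edit distance
#' to any other terminator part).
#'
#' @param n_spacers,n_modifiers,n_terminators library composition.
#' @param reads_per_design reads simulated per design at each rate.
#' @param rates substitution rates to scan.
#' @param seed master seed; everything downstream is reproducible from it.
#' @param scoring a [scoring_scheme()].
#' @return List of class `sim_study`: `config`, `per_rate` (data frame
#'   `rate`, `accuracy`, `assigned_fraction`, `te_rmse`), `per_design`
#'   (per rate and design: true and measured efficiency, accuracy,
#'   terminator min edit distance).
#' @export
run_sim_study <- function(n_spacers = 3, n_modifiers = 3, n_terminators = 6,
                          reads_per_design = 50,
                          rates = c(0, 0.05, 0.1, 0.15, 0.25), seed = 1,
                          scoring = scoring_scheme()) {
  if (any(rates < 0 | rates > 1)) stop("rates must be in [0, 1]", call. = FALSE)
  lib <- build_synthetic_library(n_spacers, n_modifiers, n_terminators,
                                 seed = seed)
  designs <- lib$designs

  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(substream_seed(seed, "true-te"))
  true_te <- stats::runif(length(designs))
  names(true_te) <- names(designs)
  models <- lapply(names(designs), function(id)
    truth_model(designs[[id]], true_te[id]))
  names(models) <- names(designs)

  term_seqs <- vapply(lib$parts$terminator, `[[`, character(1), "sequence")
  dmat <- utils::adist(term_seqs)
  diag(dmat) <- NA
  min_dist <- stats::setNames(apply(dmat, 1, min, na.rm = TRUE),
                              vapply(lib$parts$terminator, `[[`,
                                     character(1), "id"))

  per_rate <- list(); per_design <- list()
  for (rate in rates) {
    cfg <- sim_config(substitution_rate = rate,
                      reads_per_design = reads_per_design,
                      seed = substream_seed(seed, paste0("rate", rate)))
    pool <- simulate_pool(designs, models, cfg)
    res <- characterize_pool(pool, designs, scoring = scoring)
    acc <- assignment_accuracy(res$demux, pool$reads)

    a <- res$demux$assignments
    a$true_design <- pool$reads$design_id[match(a$read_id, pool$reads$read_id)]
    per_design_acc <- tapply(
      a$status == "assigned" & !is.na(a$design_id) & a$design_id == a$true_design,
      a$true_design, mean)

    meas <- res$measurements
    te_meas <- stats::setNames(meas$te_raw, meas$design_id)
    common <- intersect(names(te_meas), names(true_te))
    rmse <- sqrt(mean((te_meas[common] - true_te[common])^2))

    per_rate[[length(per_rate) + 1L]] <- data.frame(
      rate = rate, accuracy = acc,
      assigned_fraction = res$demux$summary$n_assigned /
        max(1, res$demux$summary$n_reads),
      te_rmse = rmse)
    term_of <- vapply(designs[common], `[[`, character(1), "terminator_id")
    per_design[[length(per_design) + 1L]] <- data.frame(
      rate = rate, design_id = common,
      true_te = unname(true_te[common]), te_raw = unname(te_meas[common]),
      accuracy = unname(per_design_acc[common]),
      terminator_min_dist = unname(min_dist[term_of]))
  }
  structure(list(
    config = list(n_spacers = n_spacers, n_modifiers = n_modifiers,
                  n_terminators = n_terminators,
                  reads_per_design = reads_per_design, rates = rates,
                  seed = seed),
    per_rate = do.call(rbind, per_rate),
    per_design = do.call(rbind, per_design)
  ), class = "sim_study")
}

#' @export
print.sim_study <- function(x, ...) {
  cat("<sim_study>\n")
  print(x$per_rate, row.names = FALSE)
  invisible(x)
}
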