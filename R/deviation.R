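#' Fit a measured-vs-true termination-efficiency deviation model
#'
#' Library preparation and pore entry can remove 5' portions of reads, which
#' depresses coverage at the valve start relative to the valve end and
#' biases the measured termination efficiency. This model quantifies the
#' bias by forward simulation: for each true efficiency on a grid, pools
#' are simulated under the supplied distortion settings, pushed through the
#' complete demultiplex-map-filter-profile pipeline, and the mean measured
#' efficiency recorded. [correct_te()] then inverts the measured-vs-true
#' map.
#'
#' @param designs named list of `valve_design` objects used as the
#'   simulation library.
#' @param te_grid grid of true efficiencies covering `[0, 1]` (default
#'   steps of 0.05; at least 2 points).
#' @param config a [sim_config()] carrying the distortion settings
#'   (typically a nonzero `truncation_prob`; the substitution rate defaults
#'   to 0 here because substitutions do not bias the depth ratio).
#' @param scoring a [scoring_scheme()].
#' @param monotonize enforce a non-decreasing measured-vs-true map by
#'   isotonic regression of the grid means (default `TRUE`); with `FALSE`,
#'   a non-monotone fit is kept and [correct_te()] will reject it.
#' @return An object of class `deviation_model`: data frame `grid` with
#'   `nominal_te` (the grid value), `te_true` (the realized terminated
#'   fraction of the simulated pool, used as the truth axis so the map
#'   captures pipeline distortion rather than binomial sampling),
#'   `te_measured` (monotone fit) and `te_measured_raw`, plus the
#'   settings. Calibration is most identifiable on a library with one
#'   design per terminator, so that 5'-truncated reads remain assignable
#'   rather than being censored as ties (see
#'   [build_synthetic_library()] with `n_spacers = 1, n_modifiers = 1`).
#' @export
fit_deviation_model <- function(designs, te_grid = seq(0, 1, by = 0.05),
                                config = sim_config(substitution_rate = 0,
                                                    truncation_prob = 0.2),
                                scoring = scoring_scheme(),
                                monotonize = TRUE) {
  if (length(te_grid) < 2) stop("te_grid must have at least 2 points", call. = FALSE)
  pts <- lapply(seq_along(te_grid), function(i) {
    te <- te_grid[i]
    cfg <- config
    cfg$seed <- substream_seed(config$seed, paste0("devgrid", i))
    models <- lapply(designs, truth_model, true_te = te)
    names(models) <- names(designs)
    pool <- simulate_pool(designs, models, cfg)
    res <- characterize_pool(pool, designs, scoring = scoring)
    # the truth axis is the realized terminated fraction of the simulated
    # pool, so the fitted map captures pipeline distortion only, not the
    # binomial sampling of terminated reads
    c(nominal = te, te_true = mean(pool$reads$is_terminated),
      te_measured = mean(res$measurements$te_raw, na.rm = TRUE))
  })
  g <- as.data.frame(do.call(rbind, pts))
  g <- g[order(g$te_true), ]
  measured <- g$te_measured
  fitted <- measured
  if (monotonize && is.unsorted(fitted)) {
    fitted <- stats::isoreg(g$te_true, measured)$yf
  }
  structure(list(
    grid = data.frame(nominal_te = g$nominal, te_true = g$te_true,
                      te_measured = fitted, te_measured_raw = measured),
    truncation_prob = config$truncation_prob,
    substitution_rate = config$substitution_rate,
    monotonize = monotonize
  ), class = "deviation_model")
}

#' A deviation model representing a distortion-free pipeline
#'
#' Identity measured-vs-true map; [correct_te()] under this model only
#' clamps to `[0, 1]`.
#'
#' @param te_grid grid of efficiencies.
#' @return A `deviation_model` with zero deviation everywhere.
#' @export
identity_deviation_model <- function(te_grid = seq(0, 1, by = 0.05)) {
  structure(list(grid = data.frame(nominal_te = te_grid, te_true = te_grid,
                                   te_measured = te_grid,
                                   te_measured_raw = te_grid),
                 truncation_prob = 0, substitution_rate = 0,
                 monotonize = TRUE),
            class = "deviation_model")
}

#' @export
print.deviation_model <- function(x, ...) {
  dev <- x$grid$te_measured - x$grid$te_true
  cat(sprintf(paste0("<deviation_model> %d grid points, truncation %.2f, ",
                     "deviation range [%.3f, %.3f]\n"),
              nrow(x$grid), x$truncation_prob, min(dev), max(dev)))
  invisible(x)
}

#' Correct a raw termination efficiency for pipeline deviation
#'
#' Inverts the fitted measured-vs-true map by monotone linear
#' interpolation: the corrected value is the true efficiency whose expected
#' measurement equals `te_raw`. Raw values beyond the measured range clamp
#' to the corresponding end of `[0, 1]`. Equivalent to subtracting the
#' predicted deviation when deviations are small, but better behaved when
#' they are not.
#'
#' @param te_raw raw efficiency from [compute_te()]; values outside
#'   `[-0.5, 1.5]` signal upstream corruption and raise an error.
#' @param model a `deviation_model`.
#' @return Corrected efficiency, clamped to `[0, 1]`.
#' @export
correct_te <- function(te_raw, model) {
  stopifnot(inherits(model, "deviation_model"))
  if (any(te_raw < -0.5 | te_raw > 1.5))
    stop("te_raw outside [-0.5, 1.5]; upstream corruption likely", call. = FALSE)
  g <- model$grid
  if (is.unsorted(g$te_measured))
    stop("deviation model is not monotone; refit with monotonize = TRUE",
         call. = FALSE)
  out <- stats::approx(x = g$te_measured, y = g$te_true, xout = te_raw,
                       rule = 2, ties = "ordered")$y
  pmin(pmax(out, 0), 1)
}
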