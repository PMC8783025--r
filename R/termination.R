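#' Termination efficiency from a depth profile
#'
#' The termination efficiency of a valve is the fractional drop in read
#' depth across it: `T_e = (R(x_s) - R(x_e)) / R(x_s)`, where `R(x)` is the
#' read depth at position x, `x_s` the valve start and `x_e` the first
#' position after the core terminator. The value is returned unclamped (it
#' can be slightly negative on distorted data); clamping happens only in
#' [correct_te()].
#'
#' @param profile a `depth_profile` (or a bare numeric depth vector).
#' @param x_s,x_e valve boundary positions (1-based; `x_s < x_e`, both
#'   within the reference).
#' @return Termination efficiency (numeric scalar).
#' @export
compute_te <- function(profile, x_s, x_e) {
  depth <- if (inherits(profile, "depth_profile")) profile$depth else profile
  if (x_s < 1 || x_e > length(depth) || x_s >= x_e)
    stop("require 1 <= x_s < x_e <= reference length", call. = FALSE)
  if (depth[x_s] == 0) stop("zero depth at valve start", call. = FALSE)
  (depth[x_s] - depth[x_e]) / depth[x_s]
}

#' Call termination positions from a drop profile
#'
#' The dominant termination point is the largest per-nucleotide drop within
#' the valve; secondary points are local maxima of the drop profile at or
#' above `secondary_fraction` of that maximum. Reported positions are the
#' final transcribed nucleotide (one before the position at which coverage
#' falls). Weights are the drop values renormalized over called points.
#' Ties break toward the 5'-most position.
#'
#' @param drop drop vector from [normalize_and_delta()].
#' @param x_s,x_e valve boundaries; drops at positions in `(x_s, x_e]` are
#'   considered.
#' @param secondary_fraction minimum fraction of the maximum drop for a
#'   secondary point (default 0.25).
#' @return List with `points` (data frame `position`, `weight`), `dominant`
#'   (position, `NA` when no positive drop exists) and `max_drop`.
#' @export
call_termination_points <- function(drop, x_s, x_e, secondary_fraction = 0.25) {
  idx <- seq.int(x_s + 1L, x_e)
  vals <- drop[idx]
  if (all(vals <= 0))
    return(list(points = data.frame(position = integer(0), weight = numeric(0)),
                dominant = NA_integer_, max_drop = 0))
  max_drop <- max(vals)
  is_peak <- vapply(seq_along(vals), function(i) {
    v <- vals[i]
    if (v <= 0 || v < secondary_fraction * max_drop) return(FALSE)
    left <- if (i > 1) vals[i - 1] else -Inf
    right <- if (i < length(vals)) vals[i + 1] else -Inf
    # local maximum; plateaus credit their 5'-most position
    v > left && v >= right
  }, logical(1))
  pos <- idx[is_peak]
  w <- vals[is_peak] / sum(vals[is_peak])
  dominant <- pos[which.max(vals[is_peak])]
  list(points = data.frame(position = pos - 1L, weight = w),
       dominant = dominant - 1L, max_drop = max_drop)
}

#' Count U residues in the U-tract preceding a termination point
#'
#' The U-tract is quantified as the number of U residues (T in the DNA
#' reference) in the 8-nt window ending at, and by default including, the
#' final transcribed nucleotide.
#'
#' @param reference design reference DNA string.
#' @param termination_position final transcribed nucleotide (1-based;
#'   must be >= 8).
#' @param include_final include the final transcribed base in the window
#'   (default `TRUE`); when `FALSE` the window is the 8 nt strictly before
#'   it.
#' @return Integer count in `0..8`.
#' @export
count_u_tract <- function(reference, termination_position, include_final = TRUE) {
  if (termination_position < 8)
    stop("termination position must be >= 8", call. = FALSE)
  end <- if (include_final) termination_position else termination_position - 1L
  win <- substr(reference, end - 7L, end)
  sum(seq_chars(win) == "T")
}

#' Transcript isoform stoichiometry implied by a termination efficiency
#'
#' A valve with termination efficiency `te` produces terminated and
#' read-through isoforms at ratio `te : (1 - te)`; the returned value is
#' that ratio as a real number (terminated per read-through), e.g. 1 at
#' `te = 0.5` and 11 at `te = 11/12`.
#'
#' @param te termination efficiency in `[0, 1)`.
#' @return Numeric ratio terminated : read-through.
#' @export
isoform_stoichiometry <- function(te) {
  if (any(te < 0 | te > 1)) stop("te must be in [0, 1)", call. = FALSE)
  if (any(te == 1)) stop("te = 1 leaves no read-through isoform", call. = FALSE)
  te / (1 - te)
}

#' Relative gRNA abundances along a valve-separated array
#'
#' In an array of transcription units separated by valves, the abundance of
#' unit i relative to unit 1 is the probability that a polymerase traverses
#' all upstream valves: `prod_{j < i} (1 - te_j)`.
#'
#' @param te_values ordered valve termination efficiencies, each in
#'   `[0, 1]`.
#' @return Numeric vector of length `length(te_values) + 1`, first element
#'   1, non-increasing.
#' @export
array_stoichiometry <- function(te_values) {
  if (any(te_values < 0 | te_values > 1))
    stop("te values must be in [0, 1]", call. = FALSE)
  cumprod(c(1, 1 - te_values))
}

#' Measure an array profile at each of its valves
#'
#' Applies [compute_te()] at every valve of a multi-valve array profile and
#' converts the per-valve efficiencies into relative unit abundances.
#'
#' @param profile a `depth_profile` over the array reference.
#' @param valves data frame with columns `x_s`, `x_e` (one row per valve,
#'   5' to 3').
#' @return List with `te` (per-valve efficiencies) and `abundances`
#'   (relative unit abundances, first unit = 1).
#' @export
measure_array <- function(profile, valves) {
  te <- vapply(seq_len(nrow(valves)),
               function(i) compute_te(profile, valves$x_s[i], valves$x_e[i]),
               numeric(1))
  list(te = te, abundances = array_stoichiometry(pmin(pmax(te, 0), 1)))
}

#' Full valve measurement from a profile
#'
#' Combines raw termination efficiency, termination-point calls, the
#' maximum drop and the U-tract count into one record; applies the
#' deviation correction when a model is supplied.
#'
#' @param profile a `depth_profile`.
#' @param design the corresponding `valve_design`.
#' @param deviation_model optional [fit_deviation_model()] result.
#' @param secondary_fraction passed to [call_termination_points()].
#' @return One-row data frame: `design_id`, `n_reads`, `depth_xs`,
#'   `depth_xe`, `te_raw`, `te_corrected`, `dominant_position`, `max_drop`,
#'   `u_count`, `termination_points` (encoded `"pos:weight;..."`).
#' @export
measure_valve <- function(profile, design, deviation_model = NULL,
                          secondary_fraction = 0.25) {
  nd <- normalize_and_delta(profile, design$x_s)
  te_raw <- compute_te(profile, design$x_s, design$x_e)
  calls <- call_termination_points(nd$drop, design$x_s, design$x_e,
                                   secondary_fraction)
  u <- if (is.na(calls$dominant)) NA_integer_
       else count_u_tract(design$sequence, calls$dominant)
  te_corr <- if (is.null(deviation_model)) min(max(te_raw, 0), 1)
             else correct_te(te_raw, deviation_model)
  data.frame(
    design_id = design$id, n_reads = profile$n_reads,
    depth_xs = profile$depth[design$x_s], depth_xe = profile$depth[design$x_e],
    te_raw = te_raw, te_corrected = te_corr,
    dominant_position = calls$dominant, max_drop = calls$max_drop,
    u_count = u,
    termination_points = paste(sprintf("%d:%.4f", calls$points$position,
                                       calls$points$weight), collapse = ";")
  )
}
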