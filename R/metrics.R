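#' Signed percentage deviation from a group median
#'
#' Expresses how far a design's termination efficiency lies from its part
#' group's median, as a percentage of the maximum possible deviation in
#' that direction: upward deviations are scaled by `1 - m`, downward
#' deviations by `m`, where `m` is the group median. Used to quantify how
#' strongly modifiers tune a core terminator. A symmetric alternative
#' scales both directions by `max(m, 1 - m)`.
#'
#' @param te termination efficiency.
#' @param group_median group median `m` in `[0, 1]`.
#' @param normalization `"directional"` (default) or `"symmetric"`.
#' @return Signed percentage in `[-100, 100]`. At `m` in `{0, 1}` the
#'   degenerate direction returns 0 when `te = m`, else +/-100.
#' @export
percentage_deviation <- function(te, group_median,
                                 normalization = c("directional", "symmetric")) {
  normalization <- match.arg(normalization)
  m <- group_median
  if (m < 0 || m > 1) stop("group_median must be in [0, 1]", call. = FALSE)
  if (te == m) return(0)
  denom <- switch(normalization,
                  directional = if (te > m) 1 - m else m,
                  symmetric = max(m, 1 - m))
  if (denom == 0) return(if (te > m) 100 else -100)
  100 * (te - m) / denom
}

#' Coefficient of variation of efficiencies across spacer variants
#'
#' Sample (n-1) standard deviation divided by the mean; quantifies how well
#' a modifier insulates its terminator from upstream context.
#'
#' @param te_values efficiencies of one terminator-modifier combination
#'   across spacers (at least 2 values, positive mean).
#' @return CV as a fraction.
#' @export
cv_across_spacers <- function(te_values) {
  if (length(te_values) < 2) stop("need at least 2 values", call. = FALSE)
  m <- mean(te_values)
  if (m <= 0) stop("mean must be positive", call. = FALSE)
  stats::sd(te_values) / m
}

#' Replicate agreement of termination-efficiency measurements
#'
#' @param a,b equal-length efficiency vectors from two replicates (n >= 3).
#' @param threshold absolute-difference threshold (default 0.05).
#' @return List with `r_squared` (squared Pearson correlation; `NA` when
#'   either vector has zero variance) and `fraction_within_threshold`.
#' @export
replicate_agreement <- function(a, b, threshold = 0.05) {
  if (length(a) != length(b)) stop("vectors must have equal length", call. = FALSE)
  if (length(a) < 3) stop("need n >= 3", call. = FALSE)
  r2 <- if (stats::sd(a) == 0 || stats::sd(b) == 0) NA_real_
        else stats::cor(a, b)^2
  list(r_squared = r2,
       fraction_within_threshold = mean(abs(a - b) < threshold))
}

#' Deviation between measured and predicted design frequencies
#'
#' @param measured,predicted named frequency vectors over the same designs.
#' @param cutoff absolute-percentage-deviation flag threshold (default 20).
#' @return Data frame (`design_id`, `measured`, `predicted`,
#'   `abs_pct_deviation`, `flagged`, `unpredicted`); designs with
#'   `predicted = 0` are marked `unpredicted` and excluded from
#'   percentages.
#' @export
frequency_deviation_report <- function(measured, predicted, cutoff = 20) {
  ids <- names(predicted)
  if (!setequal(ids, names(measured)))
    stop("measured and predicted must cover the same designs", call. = FALSE)
  measured <- measured[ids]
  unpred <- predicted == 0
  dev <- ifelse(unpred, NA_real_,
                abs(measured - predicted) / predicted * 100)
  data.frame(design_id = ids, measured = unname(measured),
             predicted = unname(predicted),
             abs_pct_deviation = unname(dev),
             flagged = unname(!unpred & dev > cutoff),
             unpredicted = unname(unpred), row.names = NULL)
}

#' Fold coverage of a library by a colony count
#'
#' @param colonies number of colonies picked.
#' @param n_designs number of unique designs.
#' @return colonies / n_designs.
#' @export
coverage_fold <- function(colonies, n_designs) colonies / n_designs

#' Group efficiencies into the long-format table used for tuning metrics
#'
#' @param measurements measurement data frame from [characterize_pool()].
#' @param designs the design list.
#' @return Long-format data frame (`design_id`, `spacer_id`, `modifier_id`,
#'   `terminator_id`, `te`) plus per-terminator group medians in attribute
#'   `"group_medians"`.
#' @export
grouped_te_table <- function(measurements, designs) {
  dt <- design_table(designs)
  m <- merge(dt, measurements[, c("design_id", "te_corrected")],
             by = "design_id")
  out <- data.frame(design_id = m$design_id, spacer_id = m$spacer_id,
                    modifier_id = m$modifier_id,
                    terminator_id = m$terminator_id, te = m$te_corrected)
  med <- tapply(out$te, out$terminator_id, stats::median)
  attr(out, "group_medians") <- med
  out
}
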