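#' Map one read onto its assigned design reference
#'
#' Takes the reference span of the best local alignment of the read to the
#' design and derives the quantities used by the read filter: whether the
#' span covers the full design cassette (within `end_slack` nt at either
#' end) and the 3'-most covered reference position.
#'
#' @param read DNA string (a read previously assigned to `design`).
#' @param design a `valve_design`.
#' @param scoring a [scoring_scheme()].
#' @param end_slack tolerance in nt when deciding full-cassette coverage.
#' @return One-row data frame: `rs`, `re`, `end_position` (= `re`),
#'   `contains_full_design`, `mappable`. Unmappable reads (no hit at or
#'   above `min_score`) have `mappable = FALSE` and `NA` coordinates.
#' @export
map_read <- function(read, design, scoring = scoring_scheme(), end_slack = 5) {
  hits <- seeded_align(read, design$sequence, scoring)
  if (nrow(hits) == 0)
    return(data.frame(rs = NA_integer_, re = NA_integer_,
                      end_position = NA_integer_,
                      contains_full_design = NA, mappable = FALSE))
  h <- hits[1, ]
  span_to_mapped(h$rs, h$re, design, end_slack)
}

#' @noRd
span_to_mapped <- function(rs, re, design, end_slack = 5) {
  full <- rs <= design$cassette_start + end_slack &
    re >= design$cassette_end - end_slack
  data.frame(rs = rs, re = re, end_position = re,
             contains_full_design = full, mappable = TRUE)
}

#' Build the per-design mapped-read table from pooled assignments
#'
#' Converts a [demultiplex_pool()] result into mapped-read tables, one per
#' design, reusing each read's stored best-alignment span.
#'
#' @param demux a `demux_result`.
#' @param designs named list of `valve_design` objects.
#' @param end_slack tolerance in nt for full-cassette coverage.
#' @return Named list (by design id) of data frames with columns `read_id`,
#'   `rs`, `re`, `end_position`, `contains_full_design`.
#' @export
mapped_reads_by_design <- function(demux, designs, end_slack = 5) {
  a <- demux$assignments
  a <- a[a$status == "assigned", ]
  out <- lapply(designs, function(d) {
    x <- a[a$design_id == d$id, ]
    if (nrow(x) == 0)
      return(data.frame(read_id = character(0), rs = integer(0),
                        re = integer(0), end_position = integer(0),
                        contains_full_design = logical(0)))
    full <- x$rs <= d$cassette_start + end_slack &
      x$re >= d$cassette_end - end_slack
    data.frame(read_id = x$read_id, rs = x$rs, re = x$re,
               end_position = x$re, contains_full_design = full)
  })
  names(out) <- vapply(designs, `[[`, character(1), "id")
  out
}

#' Filter mapped reads before profile construction
#'
#' A read is removed if and only if it does not contain the full design
#' cassette AND its 3' end falls between the start of the spacer and
#' `terminator_margin` nt into the core terminator — the window in which a
#' spurious truncation is indistinguishable from neither termination nor
#' read-through. Genuine terminated reads (ending deep in the terminator)
#' and read-through reads are always kept.
#'
#' @param mapped data frame from [mapped_reads_by_design()] (one design).
#' @param design the corresponding `valve_design`.
#' @param terminator_margin removal window extent into the terminator, nt
#'   (default 20).
#' @return List with `kept` (data frame) and `removed` (data frame with a
#'   `reason` column).
#' @export
filter_reads <- function(mapped, design, terminator_margin = 20) {
  if (is.na(design$spacer_start) || is.na(design$terminator_start))
    stop("design annotation lacks spacer/terminator positions", call. = FALSE)
  in_window <- mapped$end_position >= design$spacer_start &
    mapped$end_position < design$terminator_start + terminator_margin
  drop <- !mapped$contains_full_design & in_window
  removed <- mapped[drop, , drop = FALSE]
  if (nrow(removed)) removed$reason <- "truncated_in_window"
  else removed$reason <- character(0)
  list(kept = mapped[!drop, , drop = FALSE], removed = removed)
}

#' Build a read-depth profile
#'
#' Depth at position x counts the kept reads whose alignment span contains
#' x (pileup-style span coverage, terminal base included).
#'
#' @param kept data frame with `rs`, `re` columns (1-based inclusive).
#' @param reference_length length of the design reference.
#' @param design_id identifier stored in the profile.
#' @return An object of class `depth_profile`: list with `design_id`,
#'   `depth` (integer vector of length `reference_length`) and `n_reads`.
#' @export
build_depth_profile <- function(kept, reference_length, design_id = NA_character_) {
  delta <- integer(reference_length + 1L)
  if (nrow(kept)) {
    stopifnot(all(kept$rs >= 1), all(kept$re <= reference_length),
              all(kept$rs <= kept$re))
    for (i in seq_len(nrow(kept))) {
      delta[kept$rs[i]] <- delta[kept$rs[i]] + 1L
      delta[kept$re[i] + 1L] <- delta[kept$re[i] + 1L] - 1L
    }
  }
  structure(list(design_id = design_id,
                 depth = cumsum(delta[seq_len(reference_length)]),
                 n_reads = nrow(kept)),
            class = "depth_profile")
}

#' @export
print.depth_profile <- function(x, ...) {
  cat(sprintf("<depth_profile> %s: %d positions, %d reads, max depth %d\n",
              x$design_id, length(x$depth), x$n_reads,
              if (length(x$depth)) max(x$depth) else 0L))
  invisible(x)
}

#' Normalized depth and per-nucleotide drop profiles
#'
#' The normalized profile is depth divided by the depth at the valve start,
#' so drops read as fractional losses of polymerase flux. The drop profile
#' is the per-nucleotide decrease in normalized depth,
#' `D(x) = N(x-1) - N(x)` (positive where coverage falls); its peaks mark
#' termination positions, and its sum across the valve telescopes exactly
#' to the termination efficiency.
#'
#' @param profile a `depth_profile`.
#' @param x_s valve start position (depth there must be positive).
#' @return List with `normalized` and `drop` numeric vectors (same length
#'   as the profile; `drop[1]` is 0 by convention).
#' @export
normalize_and_delta <- function(profile, x_s) {
  depth <- profile$depth
  if (x_s < 1 || x_s > length(depth)) stop("x_s outside profile", call. = FALSE)
  if (depth[x_s] == 0) stop("no coverage at valve start", call. = FALSE)
  normalized <- depth / depth[x_s]
  drop <- c(0, -diff(normalized))
  list(normalized = normalized, drop = drop)
}
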