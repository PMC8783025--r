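#' Run the full characterization pipeline on a pooled read set
#'
#' Demultiplexes the reads against the design library, maps each assigned
#' read's alignment span, applies the truncation filter, builds per-design
#' depth profiles and measures every valve. This is the driver shared by
#' the analysis scripts, the simulation-study harness and the deviation
#' fit.
#'
#' @param reads reads accepted by [demultiplex_pool()] (named vector,
#'   `sim_pool`, or FASTQ path).
#' @param designs named list of `valve_design` objects.
#' @param scoring a [scoring_scheme()].
#' @param terminator_margin read-filter window, nt into the terminator.
#' @param end_slack full-cassette coverage tolerance, nt.
#' @param deviation_model optional `deviation_model` for corrected
#'   efficiencies.
#' @return List of class `valve_characterization`: `demux` (the
#'   [demultiplex_pool()] result), `profiles` (named list of
#'   `depth_profile`), `measurements` (data frame, one row per design with
#'   coverage at the valve start; designs without usable coverage are
#'   reported in `skipped`), `removed` (per-design filtered-read counts).
#' @export
characterize_pool <- function(reads, designs, scoring = scoring_scheme(),
                              terminator_margin = 20, end_slack = 5,
                              deviation_model = NULL) {
  demux <- demultiplex_pool(reads, designs, scoring)
  mapped <- mapped_reads_by_design(demux, designs, end_slack)

  profiles <- list()
  removed <- integer(length(designs))
  names(removed) <- names(mapped)
  rows <- list()
  skipped <- character(0)

  for (id in names(mapped)) {
    d <- designs[[id]]
    flt <- filter_reads(mapped[[id]], d, terminator_margin)
    removed[id] <- nrow(flt$removed)
    prof <- build_depth_profile(flt$kept, nchar(d$sequence), id)
    profiles[[id]] <- prof
    if (prof$depth[d$x_s] > 0) {
      rows[[id]] <- measure_valve(prof, d, deviation_model)
    } else {
      skipped <- c(skipped, id)
    }
  }
  measurements <- if (length(rows)) do.call(rbind, rows) else
    data.frame(design_id = character(0))
  rownames(measurements) <- NULL
  structure(list(demux = demux, profiles = profiles,
                 measurements = measurements, removed = removed,
                 skipped = skipped),
            class = "valve_characterization")
}

#' Assignment accuracy of a demultiplexing run against simulation truth
#'
#' @param demux a `demux_result`.
#' @param truth data frame with `read_id` and true `design_id` (e.g.
#'   `pool$reads`).
#' @param denominator `"assigned"` (fraction of assigned reads that are
#'   correct) or `"all"` (fraction of all reads assigned correctly).
#' @return Accuracy in `[0, 1]`.
#' @export
assignment_accuracy <- function(demux, truth,
                                denominator = c("assigned", "all")) {
  denominator <- match.arg(denominator)
  a <- demux$assignments
  m <- merge(a, truth[, c("read_id", "design_id")], by = "read_id",
             suffixes = c("", ".true"))
  correct <- m$status == "assigned" & m$design_id == m$design_id.true
  denom <- if (denominator == "assigned") sum(m$status == "assigned") else nrow(m)
  if (denom == 0) return(NA_real_)
  sum(correct, na.rm = TRUE) / denom
}

#' Write the per-design measurement table and profiles to disk
#'
#' @param result a `valve_characterization`.
#' @param dir output directory (created if needed); writes
#'   `measurements.tsv` and one `<design>.profile.tsv` per design with
#'   columns `position`, `depth`, `normalized`, `drop`.
#' @param designs the design list used to produce `result`.
#' @return Invisibly, `dir`.
#' @export
write_characterization <- function(result, dir, designs) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv_table(result$measurements, file.path(dir, "measurements.tsv"))
  for (id in names(result$profiles)) {
    prof <- result$profiles[[id]]
    d <- designs[[id]]
    if (prof$depth[d$x_s] > 0) {
      nd <- normalize_and_delta(prof, d$x_s)
      tab <- data.frame(position = seq_along(prof$depth), depth = prof$depth,
                        normalized = nd$normalized, drop = nd$drop)
    } else {
      tab <- data.frame(position = seq_along(prof$depth), depth = prof$depth,
                        normalized = NA_real_, drop = NA_real_)
    }
    write_tsv_table(tab, file.path(dir, paste0(id, ".profile.tsv")))
  }
  invisible(dir)
}
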