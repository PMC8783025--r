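#' Build a guide-RNA array template with internal transcriptional valves
#'
#' Constructs the reference for an array of `n_units` transcription units
#' (e.g. gRNAs) separated by core-terminator valves, so that the relative
#' abundance of downstream units is set by the upstream valves'
#' termination efficiencies. Unit sequences and flanks are generated
#' padding; terminators come from [generate_terminator()] unless supplied.
#'
#' @param n_units number of transcription units (valves = `n_units - 1`).
#' @param seed integer seed for all generated sequence.
#' @param unit_length length of each unit in nt.
#' @param terminators optional list of `valve_part` terminators (length
#'   `n_units - 1`).
#' @param flank5_length,flank3_length flank lengths in nt.
#' @return An object of class `grna_array`: list with `id`, `sequence`,
#'   `valves` (data frame `x_s`, `x_e`, `termination_position` per valve)
#'   and `units` (data frame `start`, `end`).
#' @export
build_grna_array <- function(n_units = 3, seed = 1, unit_length = 30,
                             terminators = NULL, flank5_length = 30,
                             flank3_length = 50) {
  stopifnot(n_units >= 2)
  n_valves <- n_units - 1L
  if (is.null(terminators))
    terminators <- lapply(seq_len(n_valves), function(i)
      generate_terminator(seed = substream_seed(seed, paste0("arrT", i)),
                          id = paste0("AT", i)))
  stopifnot(length(terminators) == n_valves)

  seqs <- character(0)
  pos <- 1L
  units <- data.frame(start = integer(0), end = integer(0))
  valves <- data.frame(x_s = integer(0), x_e = integer(0),
                       termination_position = integer(0))
  add <- function(s) { seqs <<- c(seqs, s); p <- pos; pos <<- pos + nchar(s); p }

  add(generate_padding(flank5_length, seed = substream_seed(seed, "arrF5")))
  for (i in seq_len(n_units)) {
    us <- add(generate_padding(unit_length,
                               seed = substream_seed(seed, paste0("arrU", i))))
    units <- rbind(units, data.frame(start = us, end = pos - 1L))
    if (i <= n_valves) {
      tseq <- terminators[[i]]$sequence
      ts <- add(tseq)
      tlen <- nchar(tseq)
      valves <- rbind(valves, data.frame(
        x_s = ts, x_e = ts + tlen,
        termination_position = ts + min(tlen - 1L, floor(3 * tlen / 4))))
    }
  }
  add(generate_padding(flank3_length, seed = substream_seed(seed, "arrF3")))

  structure(list(id = sprintf("array%dx%d", n_units, as.integer(seed)),
                 sequence = paste(seqs, collapse = ""),
                 valves = valves, units = units),
            class = "grna_array")
}

#' Simulate reads from a gRNA array
#'
#' Each polymerase traverses the valves 5' to 3' and terminates at valve i
#' (at its termination position) with probability `te_values[i]`,
#' independently; otherwise it transcribes the full array. Poly(A) tails
#' and substitution errors are applied as in [simulate_pool()].
#'
#' @param array a [build_grna_array()] object.
#' @param te_values per-valve true termination efficiencies.
#' @param n_reads number of reads.
#' @param seed integer seed.
#' @param substitution_rate per-base substitution probability.
#' @param polyA_length appended tail length.
#' @return Data frame `read_id`, `sequence`, `end_valve` (0 =
#'   read-through), `end_position`.
#' @export
simulate_array_pool <- function(array, te_values, n_reads, seed = 1,
                                substitution_rate = 0, polyA_length = 30) {
  stopifnot(inherits(array, "grna_array"),
            length(te_values) == nrow(array$valves))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(substream_seed(seed, array$id))
  L <- nchar(array$sequence)
  seq_v <- character(n_reads); endv <- integer(n_reads); endp <- integer(n_reads)
  for (i in seq_len(n_reads)) {
    stop_at <- 0L
    for (j in seq_along(te_values)) {
      if (stats::runif(1) < te_values[j]) { stop_at <- j; break }
    }
    end <- if (stop_at > 0) array$valves$termination_position[stop_at] else L
    s <- paste0(substr(array$sequence, 1, end), strrep("A", polyA_length))
    seq_v[i] <- apply_substitutions(s, substitution_rate)
    endv[i] <- stop_at; endp[i] <- end
  }
  data.frame(read_id = sprintf("%s|r%05d", array$id, seq_len(n_reads)),
             sequence = seq_v, end_valve = endv, end_position = endp)
}

#' Profile an array read pool and measure its valves
#'
#' Aligns every read to the array reference with the seeded aligner,
#' builds the depth profile, and measures each valve's termination
#' efficiency and the resulting unit stoichiometry.
#'
#' @param pool data frame from [simulate_array_pool()] (or any with a
#'   `sequence` column).
#' @param array a `grna_array`.
#' @param scoring a [scoring_scheme()].
#' @return List with `profile` (a `depth_profile`), `te` and `abundances`
#'   (from [measure_array()]), and `n_unmapped`.
#' @export
characterize_array <- function(pool, array, scoring = scoring_scheme()) {
  spans <- lapply(pool$sequence, function(s) {
    hits <- seeded_align(s, array$sequence, scoring)
    if (nrow(hits) == 0) NULL else hits[1, c("rs", "re")]
  })
  keep <- !vapply(spans, is.null, logical(1))
  kept <- do.call(rbind, spans[keep])
  profile <- build_depth_profile(kept, nchar(array$sequence), array$id)
  m <- measure_array(profile, array$valves)
  list(profile = profile, te = m$te, abundances = m$abundances,
       n_unmapped = sum(!keep))
}
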