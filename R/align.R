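#' Alignment scoring scheme
#'
#' Raw-score parameterization of the local aligner used for
#' intrinsic-barcode demultiplexing: match +2, mismatch -3, affine gaps with
#' a gap of length k costing `gap_open + k * gap_extend` (5 + 2k), and
#' exact-match seeds of `word_size` 4. These values mirror a BLASTN-style
#' nucleotide scoring with small word size suitable for ~15%-error long
#' reads. Ranking designs by raw score is equivalent to ranking by bitscore,
#' since at fixed scoring parameters the bitscore is a fixed increasing
#' affine transform of the raw score.
#'
#' @param match match reward (> 0).
#' @param mismatch mismatch penalty (negative).
#' @param gap_open,gap_extend nonnegative affine gap costs.
#' @param word_size exact seed length for the seeded aligner.
#' @param min_score minimum raw score for a reported hit (default 30,
#'   roughly 15 matched nt; replaces an e-value gate).
#' @param band_width half-width of the banded extension around seed
#'   diagonals (default 16).
#' @param small_cutoff problems with `n * m` at or below this extend every
#'   seed diagonal; larger problems demand corroborated diagonals.
#' @param rel_frac for large problems, keep diagonals holding at least this
#'   fraction of the best diagonal's seed count (minimum 2 seeds).
#' @param shortlist_word exact word length of the pooled demultiplexer's
#'   candidate screen.
#' @param shortlist_k number of candidate designs scored per read after the
#'   screen (ties with the screen maximum are always kept).
#' @return An object of class `scoring_scheme`.
#' @export
scoring_scheme <- function(match = 2, mismatch = -3, gap_open = 5,
                           gap_extend = 2, word_size = 4, min_score = 30,
                           band_width = 16, small_cutoff = 10000,
                           rel_frac = 0.05, shortlist_word = 10,
                           shortlist_k = 8) {
  stopifnot(match > 0, mismatch < 0, gap_open >= 0, gap_extend >= 0,
            word_size >= 1)
  structure(list(match = as.integer(match), mismatch = as.integer(mismatch),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 word_size = as.integer(word_size),
                 min_score = as.integer(min_score),
                 band_width = as.integer(band_width),
                 small_cutoff = as.integer(small_cutoff),
                 rel_frac = rel_frac,
                 shortlist_word = as.integer(shortlist_word),
                 shortlist_k = as.integer(shortlist_k)),
            class = "scoring_scheme")
}

#' Optimal local alignment by full dynamic programming
#'
#' Exact affine-gap Smith-Waterman over the full DP matrix; the reference
#' oracle for the seeded aligner. Ties between equal-scoring alignments are
#' broken toward the lowest reference start, then lowest query start.
#'
#' @param query,reference DNA strings (nonempty).
#' @param scoring a [scoring_scheme()].
#' @return A list with `score`, `qs`, `qe`, `rs`, `re` (1-based inclusive
#'   query/reference intervals). A score of 0 means no positive-scoring
#'   local alignment exists.
#' @export
local_align_dp <- function(query, reference, scoring = scoring_scheme()) {
  assert_dna(query, "query"); assert_dna(reference, "reference")
  if (nchar(query) == 0 || nchar(reference) == 0)
    stop("empty sequence", call. = FALSE)
  cpp_local_align(query, reference, scoring$match, scoring$mismatch,
                  scoring$gap_open, scoring$gap_extend)
}

#' Seeded local alignment
#'
#' Finds exact `word_size`-mer seeds, clusters their diagonals, and runs a
#' banded affine-gap extension around each cluster. Reported scores never
#' exceed the full-DP optimum ([local_align_dp()]) and equal it whenever the
#' optimal alignment lies within a band of a corroborated seed diagonal.
#'
#' @inheritParams local_align_dp
#' @return Data frame of hits (`score`, `qs`, `qe`, `rs`, `re`), best
#'   first; zero rows when no seed produces a hit at or above `min_score`.
#' @export
seeded_align <- function(query, reference, scoring = scoring_scheme()) {
  assert_dna(query, "query"); assert_dna(reference, "reference")
  if (nchar(query) == 0 || nchar(reference) == 0)
    stop("empty sequence", call. = FALSE)
  cpp_seeded_align(query, reference, scoring$match, scoring$mismatch,
                   scoring$gap_open, scoring$gap_extend, scoring$word_size,
                   scoring$band_width, scoring$min_score,
                   scoring$small_cutoff, scoring$rel_frac)
}

#' Assign one read to its best-matching design
#'
#' Scores the read against every design with the seeded aligner and keeps
#' the design with the maximum raw score. Reads with no hit at or above
#' `min_score` are `unassigned_no_hit`; reads whose top score is shared by
#' two or more designs are `unassigned_tie` (so assignment is invariant to
#' design order).
#'
#' @param read DNA string.
#' @param design_seqs named character vector of design reference sequences.
#' @param scoring a [scoring_scheme()].
#' @return One-row data frame: `status`, `design_id`, `score`, `rs`, `re`,
#'   `qs`, `qe`.
#' @export
assign_read <- function(read, design_seqs, scoring = scoring_scheme()) {
  stopifnot(length(design_seqs) >= 1)
  res <- cpp_demux(read, unname(design_seqs), scoring$match, scoring$mismatch,
                   scoring$gap_open, scoring$gap_extend, scoring$word_size,
                   scoring$band_width, scoring$min_score,
                   scoring$small_cutoff, scoring$rel_frac,
                   scoring$shortlist_word, length(design_seqs))
  data.frame(
    status = if (res$tie[1]) "unassigned_tie"
             else if (is.na(res$design_index[1])) "unassigned_no_hit"
             else "assigned",
    design_id = if (is.na(res$design_index[1])) NA_character_
                else names(design_seqs)[res$design_index[1]],
    score = res$score[1], rs = res$rs[1], re = res$re[1],
    qs = res$qs[1], qe = res$qe[1]
  )
}

#' Demultiplex a pooled read set against a design library
#'
#' Assigns every read to the design with the best seeded-alignment raw
#' score. A long-word diagonal screen shortlists `shortlist_k` candidate
#' designs per read (always including all designs tied at the screen
#' maximum, so duplicate designs still surface as ties) before full seeded
#' scoring.
#'
#' @param reads named character vector of read sequences, a `sim_pool`, or
#'   a FASTQ path.
#' @param designs named list of `valve_design` objects (or a named
#'   character vector of reference sequences).
#' @param scoring a [scoring_scheme()].
#' @return List of class `demux_result` with `assignments` (data frame:
#'   `read_id`, `status`, `design_id`, `score`, `rs`, `re`, `qs`, `qe`) and
#'   `summary` (status counts and per-design assigned-read counts and
#'   frequencies relative to total assigned reads).
#' @export
demultiplex_pool <- function(reads, designs, scoring = scoring_scheme()) {
  reads <- as_read_vector(reads)
  seqs <- as_design_sequences(designs)
  if (length(reads) == 0) {
    assignments <- data.frame(read_id = character(0), status = character(0),
                              design_id = character(0), score = integer(0),
                              rs = integer(0), re = integer(0),
                              qs = integer(0), qe = integer(0))
  } else {
    res <- cpp_demux(unname(reads), unname(seqs), scoring$match,
                     scoring$mismatch, scoring$gap_open, scoring$gap_extend,
                     scoring$word_size, scoring$band_width, scoring$min_score,
                     scoring$small_cutoff, scoring$rel_frac,
                     scoring$shortlist_word, scoring$shortlist_k)
    status <- ifelse(res$tie, "unassigned_tie",
                     ifelse(is.na(res$design_index), "unassigned_no_hit",
                            "assigned"))
    assignments <- data.frame(
      read_id = names(reads), status = status,
      design_id = ifelse(is.na(res$design_index), NA_character_,
                         names(seqs)[res$design_index]),
      score = res$score, rs = res$rs, re = res$re, qs = res$qs, qe = res$qe
    )
  }
  assigned <- assignments[assignments$status == "assigned", ]
  per_design <- table(factor(assigned$design_id, levels = names(seqs)))
  structure(list(
    assignments = assignments,
    summary = list(
      n_reads = nrow(assignments),
      n_assigned = nrow(assigned),
      n_no_hit = sum(assignments$status == "unassigned_no_hit"),
      n_tie = sum(assignments$status == "unassigned_tie"),
      per_design_counts = per_design,
      per_design_frequency = if (nrow(assigned) > 0)
        as.numeric(per_design) / nrow(assigned) else rep(0, length(seqs))
    )
  ), class = "demux_result")
}

#' @noRd
as_read_vector <- function(reads) {
  if (inherits(reads, "sim_pool"))
    return(stats::setNames(reads$reads$sequence, reads$reads$read_id))
  if (is.character(reads) && length(reads) == 1 && file.exists(reads) &&
      grepl("\\.(fastq|fq)(\\.gz)?$", reads))
    return(read_fastq_sequences(reads))
  if (is.character(reads)) {
    if (is.null(names(reads)))
      names(reads) <- sprintf("read%05d", seq_along(reads))
    return(reads)
  }
  stop("unsupported reads input", call. = FALSE)
}

#' @noRd
as_design_sequences <- function(designs) {
  if (is.character(designs)) {
    stopifnot(!is.null(names(designs)))
    return(designs)
  }
  stats::setNames(vapply(designs, `[[`, character(1), "sequence"),
                  vapply(designs, `[[`, character(1), "id"))
}
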