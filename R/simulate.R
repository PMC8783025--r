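#' Ground-truth model for one design
#'
#' Defines the true termination behaviour used by the read simulator: the
#' true termination efficiency, the distribution of final transcribed
#' positions within the core terminator, and the poly(A) tail length
#' appended to every transcript.
#'
#' @param design a `valve_design`.
#' @param true_te true termination efficiency in `[0, 1]`.
#' @param termination_weights optional named numeric: positions (1-based,
#'   within the terminator interval) mapped to weights summing to 1. The
#'   position is the final transcribed nucleotide. Default: a single
#'   position at the middle of the terminator's 3' half, i.e. just past the
#'   hairpin inside the U-tract region.
#' @param polyA_length poly(A) tail length in nt (default 30).
#' @return An object of class `truth_model`.
#' @export
truth_model <- function(design, true_te, termination_weights = NULL,
                        polyA_length = 30) {
  stopifnot(inherits(design, "valve_design"))
  if (true_te < 0 || true_te > 1) stop("true_te must be in [0, 1]", call. = FALSE)
  ts <- design$terminator_start; te_end <- design$terminator_end
  if (is.null(termination_weights)) {
    len <- te_end - ts + 1L
    pos <- ts + min(len - 1L, floor(3 * len / 4))
    termination_weights <- stats::setNames(1, pos)
  }
  pos <- as.integer(names(termination_weights))
  if (any(pos < ts | pos > te_end))
    stop("termination positions must lie within the terminator interval [",
         ts, ", ", te_end, "]", call. = FALSE)
  if (abs(sum(termination_weights) - 1) > 1e-9)
    stop("termination weights must sum to 1", call. = FALSE)
  structure(list(design_id = design$id, true_te = true_te,
                 termination_weights = termination_weights,
                 polyA_length = as.integer(polyA_length)),
            class = "truth_model")
}

#' Simulation settings for a pooled dRNA-seq run
#'
#' @param substitution_rate per-base probability of a random substitution to
#'   one of the three other bases (default 0.15, the error level typical of
#'   nanopore dRNA-seq basecalls).
#' @param truncation_prob probability that a read loses a random 5' prefix,
#'   emulating library-preparation and pore-entry artifacts (default 0).
#' @param reads_per_design integer, or named integer vector per design id.
#' @param seed integer master seed; each design draws from its own
#'   substream so pools are reproducible and order-independent.
#' @param min_kept_length minimum read length retained after truncation.
#' @param design_frequency_mode `"uniform"` (every design gets
#'   `reads_per_design` reads) or `"from_part_freqs"` (the pool total
#'   `reads_per_design * n_designs` is multinomially allocated according to
#'   frequencies predicted from `part_freqs`).
#' @param part_freqs part-frequency list for `"from_part_freqs"` mode (see
#'   [predict_design_frequencies()]).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(substitution_rate = 0.15, truncation_prob = 0,
                       reads_per_design = 100, seed = 1,
                       min_kept_length = 30,
                       design_frequency_mode = c("uniform", "from_part_freqs"),
                       part_freqs = NULL) {
  if (substitution_rate < 0 || substitution_rate > 1)
    stop("substitution_rate must be in [0, 1]", call. = FALSE)
  if (truncation_prob < 0 || truncation_prob > 1)
    stop("truncation_prob must be in [0, 1]", call. = FALSE)
  if (any(reads_per_design < 0)) stop("reads_per_design must be >= 0", call. = FALSE)
  structure(list(substitution_rate = substitution_rate,
                 truncation_prob = truncation_prob,
                 reads_per_design = reads_per_design,
                 seed = as.integer(seed),
                 min_kept_length = as.integer(min_kept_length),
                 design_frequency_mode = match.arg(design_frequency_mode),
                 part_freqs = part_freqs),
            class = "sim_config")
}

#' Simulate one error-free transcript read
#'
#' With probability `true_te` the polymerase terminates at a position drawn
#' from the model's termination-weight distribution and the read is the
#' reference prefix up to and including that base; otherwise the full
#' reference is transcribed. A poly(A) tail is appended either way. Uses the
#' current R random number generator state.
#'
#' @param design a `valve_design`.
#' @param model its [truth_model()].
#' @return A list with `sequence`, `is_terminated`, `termination_position`
#'   (final transcribed base, `NA` for read-through) and
#'   `truncation_position` (`NA`; see [apply_truncation()]).
#' @export
simulate_transcript <- function(design, model) {
  terminated <- stats::runif(1) < model$true_te
  if (terminated) {
    w <- model$termination_weights
    pos <- if (length(w) == 1L) as.integer(names(w)) else
      as.integer(sample(names(w), 1, prob = w))
    body <- substr(design$sequence, 1, pos)
  } else {
    pos <- NA_integer_
    body <- design$sequence
  }
  list(sequence = paste0(body, strrep("A", model$polyA_length)),
       is_terminated = terminated, termination_position = pos,
       truncation_position = NA_integer_)
}

#' Apply random substitutions to a sequence
#'
#' Each position is independently substituted, with probability `rate`, to
#' one of the three other bases chosen uniformly. Length is preserved.
#'
#' @param seq DNA string.
#' @param rate substitution probability per base, in `[0, 1]`.
#' @return The mutated sequence.
#' @export
apply_substitutions <- function(seq, rate) {
  if (rate < 0 || rate > 1) stop("rate must be in [0, 1]", call. = FALSE)
  if (rate == 0 || nchar(seq) == 0) return(seq)
  chars <- seq_chars(seq)
  hit <- stats::runif(length(chars)) < rate
  if (any(hit)) {
    alt <- vapply(chars[hit], function(b) sample(setdiff(DNA_BASES, b), 1),
                  character(1))
    chars[hit] <- alt
  }
  paste(chars, collapse = "")
}

#' Apply optional 5' truncation to a simulated read
#'
#' With probability `prob` the read loses a 5' prefix whose length is drawn
#' uniformly over `[1, len - min_kept]`; the 3' end is never altered. When
#' no legal cut exists (`len <= min_kept`) the read is returned unchanged.
#'
#' @param read a read list as returned by [simulate_transcript()].
#' @param prob truncation probability in `[0, 1]`.
#' @param min_kept minimum retained read length.
#' @return The read, with `truncation_position` set to the number of bases
#'   removed when truncation occurred.
#' @export
apply_truncation <- function(read, prob, min_kept = 30) {
  if (prob < 0 || prob > 1) stop("prob must be in [0, 1]", call. = FALSE)
  if (prob == 0) return(read)
  len <- nchar(read$sequence)
  max_cut <- len - min_kept
  if (max_cut < 1) return(read)
  if (stats::runif(1) < prob) {
    cut <- sample.int(max_cut, 1)
    read$sequence <- substr(read$sequence, cut + 1, len)
    read$truncation_position <- cut
  }
  read
}

#' Simulate a pooled dRNA-seq run over a design library
#'
#' Generates reads for every design according to the configuration, applying
#' termination, poly(A) tailing, substitution errors and optional 5'
#' truncation, with a per-design RNG substream derived from the master seed
#' (so adding designs never perturbs the reads of existing ones).
#'
#' @param designs named list of `valve_design` objects.
#' @param models named list of [truth_model()] objects, one per design.
#' @param config a [sim_config()].
#' @return An object of class `sim_pool`: a list with `reads` (data frame:
#'   `read_id`, `sequence`, `design_id`, `is_terminated`,
#'   `termination_position`, `truncation_position`) and the `config`.
#' @export
simulate_pool <- function(designs, models, config) {
  stopifnot(inherits(config, "sim_config"))
  ids <- vapply(designs, `[[`, character(1), "id")
  missing <- setdiff(ids, names(models))
  if (length(missing))
    stop("missing truth model for design(s): ",
         paste(missing, collapse = ", "), call. = FALSE)

  n_per <- resolve_read_counts(designs, config)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))

  out <- vector("list", length(designs))
  for (k in seq_along(designs)) {
    d <- designs[[k]]
    n <- n_per[[d$id]]
    if (n == 0) { out[[k]] <- NULL; next }
    set.seed(substream_seed(config$seed, d$id))
    m <- models[[d$id]]
    seq_v <- character(n); term_v <- logical(n)
    pos_v <- integer(n); trunc_v <- integer(n)
    for (i in seq_len(n)) {
      r <- simulate_transcript(d, m)
      r <- apply_truncation(r, config$truncation_prob, config$min_kept_length)
      seq_v[i] <- apply_substitutions(r$sequence, config$substitution_rate)
      term_v[i] <- r$is_terminated
      pos_v[i] <- r$termination_position
      trunc_v[i] <- r$truncation_position
    }
    out[[k]] <- data.frame(
      read_id = sprintf("%s|r%04d", d$id, seq_len(n)),
      sequence = seq_v, design_id = d$id, is_terminated = term_v,
      termination_position = pos_v, truncation_position = trunc_v
    )
  }
  reads <- do.call(rbind, out)
  rownames(reads) <- NULL
  structure(list(reads = reads, config = config), class = "sim_pool")
}

#' @noRd
resolve_read_counts <- function(designs, config) {
  ids <- vapply(designs, `[[`, character(1), "id")
  rpd <- config$reads_per_design
  if (config$design_frequency_mode == "from_part_freqs") {
    if (is.null(config$part_freqs))
      stop("part_freqs required for design_frequency_mode 'from_part_freqs'",
           call. = FALSE)
    pf <- predict_design_frequencies(config$part_freqs, designs)
    total <- if (length(rpd) == 1L) rpd * length(designs) else sum(rpd)
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
    set.seed(substream_seed(config$seed, "design-frequencies"))
    counts <- as.integer(stats::rmultinom(1, total, pf[ids]))
    return(stats::setNames(as.list(counts), ids))
  }
  if (length(rpd) == 1L) return(stats::setNames(as.list(rep(rpd, length(ids))), ids))
  missing <- setdiff(ids, names(rpd))
  if (length(missing))
    stop("reads_per_design missing designs: ", paste(missing, collapse = ", "),
         call. = FALSE)
  stats::setNames(as.list(as.integer(rpd[ids])), ids)
}

#' Write a simulated pool as FASTQ plus a ground-truth table
#'
#' FASTQ qualities are a constant placeholder (`I`), as no quality model is
#' simulated. The truth TSV has one row per read.
#'
#' @param pool a `sim_pool`.
#' @param fastq_path,truth_path output paths.
#' @return Invisibly, the two paths.
#' @export
write_pool <- function(pool, fastq_path, truth_path) {
  stopifnot(inherits(pool, "sim_pool"))
  seqs <- Biostrings::DNAStringSet(pool$reads$sequence)
  names(seqs) <- pool$reads$read_id
  quals <- Biostrings::BStringSet(strrep("I", nchar(pool$reads$sequence)))
  Biostrings::writeXStringSet(seqs, fastq_path, format = "fastq",
                              qualities = quals)
  write_tsv_table(pool$reads[, c("read_id", "design_id", "is_terminated",
                                 "termination_position", "truncation_position")],
                  truth_path)
  invisible(c(fastq_path, truth_path))
}

#' Read a FASTQ file as a named vector of read sequences
#'
#' @param path FASTQ file.
#' @return Named character vector (names are read ids).
#' @export
read_fastq_sequences <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path, format = "fastq")
  stats::setNames(as.character(seqs), sub("\\s.*$", "", names(seqs)))
}
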