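#' Assemble a single transcriptional-valve design
#'
#' A design is the exact concatenation of a 5' fixed flank, an optional
#' spacer, an optional modifier, a core terminator and a 3' fixed flank.
#' Part intervals are recorded in 1-based inclusive coordinates on the
#' reference. The transcriptional valve spans from `x_s`, the first base of
#' the modifier (or of the terminator when no modifier is present), to
#' `x_e`, the first base after the core terminator; read depth immediately
#' before and after the valve is compared at these two positions.
#'
#' @param spacer,modifier `valve_part` or `NULL`.
#' @param terminator `valve_part` of role `"terminator"`.
#' @param flank5,flank3 fixed flanking DNA (may be empty; a nonempty
#'   `flank3` is required downstream so that read-through coverage at `x_e`
#'   is observable).
#' @param id design identifier; default joins part ids with underscores.
#' @return An object of class `valve_design`: a list with the reference
#'   sequence, a part-interval table, valve boundaries `x_s`/`x_e`, and the
#'   cassette interval (first to last part base).
#' @export
valve_design <- function(terminator, modifier = NULL, spacer = NULL,
                         flank5 = "", flank3 = "", id = NULL) {
  stopifnot(inherits(terminator, "valve_part"))
  if (terminator$role != "terminator")
    stop("'terminator' must have role terminator", call. = FALSE)
  assert_dna(flank5, "flank5"); assert_dna(flank3, "flank3")

  used <- Filter(Negate(is.null), list(spacer = spacer, modifier = modifier,
                                       terminator = terminator))
  if (is.null(id))
    id <- paste(vapply(used, `[[`, character(1), "id"), collapse = "_")

  pos <- nchar(flank5) + 1L
  iv <- data.frame(part_id = character(0), role = character(0),
                   start = integer(0), end = integer(0))
  for (nm in names(used)) {
    p <- used[[nm]]
    len <- nchar(p$sequence)
    iv <- rbind(iv, data.frame(part_id = p$id, role = p$role,
                               start = pos, end = pos + len - 1L))
    pos <- pos + len
  }
  ref <- paste0(flank5, paste(vapply(used, `[[`, character(1), "sequence"),
                              collapse = ""), flank3)

  term_row <- iv[iv$role == "terminator", ]
  mod_row <- iv[iv$role == "modifier", ]
  x_s <- if (nrow(mod_row)) mod_row$start else term_row$start
  x_e <- term_row$end + 1L

  structure(list(
    id = id,
    spacer_id = if (is.null(spacer)) NA_character_ else spacer$id,
    modifier_id = if (is.null(modifier)) NA_character_ else modifier$id,
    terminator_id = terminator$id,
    sequence = ref,
    intervals = iv,
    x_s = as.integer(x_s), x_e = as.integer(x_e),
    cassette_start = as.integer(min(iv$start)),
    cassette_end = as.integer(max(iv$end)),
    spacer_start = if (nrow(iv[iv$role == "spacer", ])) as.integer(iv$start[iv$role == "spacer"]) else as.integer(min(iv$start)),
    terminator_start = as.integer(term_row$start),
    terminator_end = as.integer(term_row$end)
  ), class = "valve_design")
}

#' @export
print.valve_design <- function(x, ...) {
  cat(sprintf("<valve_design> %s: %d nt, valve [%d, %d)\n",
              x$id, nchar(x$sequence), x$x_s, x$x_e))
  invisible(x)
}

#' Enumerate the combinatorial design library
#'
#' Builds the full Cartesian product spacer x modifier x terminator from a
#' part set; roles with no parts are skipped rather than multiplying the
#' library by zero. With the published part counts (7 spacers, 13 modifiers,
#' 13 terminators) this yields 1183 unique designs.
#'
#' @param parts a [part_set()].
#' @param flank5,flank3 fixed flanks shared by every design.
#' @return List of `valve_design` objects, with deterministic ids
#'   `<spacer>_<modifier>_<terminator>` (missing roles omitted).
#' @export
enumerate_designs <- function(parts, flank5 = "", flank3 = "") {
  stopifnot(inherits(parts, "part_set"))
  if (length(parts$terminator) == 0) stop("no terminators", call. = FALSE)
  spacers <- if (length(parts$spacer)) parts$spacer else list(NULL)
  modifiers <- if (length(parts$modifier)) parts$modifier else list(NULL)

  designs <- list()
  for (s in spacers)
    for (m in modifiers)
      for (t in parts$terminator)
        designs[[length(designs) + 1L]] <-
          valve_design(t, modifier = m, spacer = s,
                       flank5 = flank5, flank3 = flank3)
  names(designs) <- vapply(designs, `[[`, character(1), "id")
  if (anyDuplicated(names(designs)))
    stop("duplicate design ids in enumeration", call. = FALSE)
  designs
}

#' Summarize a design list as a data frame
#'
#' @param designs list of `valve_design` objects.
#' @return data frame with one row per design (ids, part ids, length, valve
#'   boundaries).
#' @export
design_table <- function(designs) {
  data.frame(
    design_id = vapply(designs, `[[`, character(1), "id"),
    spacer_id = vapply(designs, `[[`, character(1), "spacer_id"),
    modifier_id = vapply(designs, `[[`, character(1), "modifier_id"),
    terminator_id = vapply(designs, `[[`, character(1), "terminator_id"),
    length = vapply(designs, function(d) nchar(d$sequence), integer(1)),
    x_s = vapply(designs, `[[`, integer(1), "x_s"),
    x_e = vapply(designs, `[[`, integer(1), "x_e"),
    row.names = NULL
  )
}

#' Predict design frequencies from part frequencies
#'
#' Under independent combinatorial assembly the expected frequency of a
#' design is the product of its constituent parts' frequencies.
#'
#' @param part_freqs named list with elements `spacer`, `modifier`,
#'   `terminator` (those present in the designs); each a named numeric
#'   vector of per-part frequencies summing to 1.
#' @param designs list of `valve_design` objects.
#' @return Named numeric vector of predicted design frequencies. Sums to 1
#'   over a full product library.
#' @export
predict_design_frequencies <- function(part_freqs, designs) {
  for (role in names(part_freqs)) {
    f <- part_freqs[[role]]
    if (any(f < 0)) stop("negative part frequency in role ", role, call. = FALSE)
    if (abs(sum(f) - 1) > 1e-9)
      stop("part frequencies for role ", role, " do not sum to 1", call. = FALSE)
  }
  res <- vapply(designs, function(d) {
    f <- 1
    for (role in c("spacer", "modifier", "terminator")) {
      pid <- d[[paste0(role, "_id")]]
      if (is.na(pid)) next
      rf <- part_freqs[[role]]
      if (is.null(rf) || is.na(rf[pid]))
        stop("part '", pid, "' (", role, ") missing from part_freqs",
             call. = FALSE)
      f <- f * unname(rf[pid])
    }
    f
  }, numeric(1))
  stats::setNames(res, vapply(designs, `[[`, character(1), "id"))
}

#' Write designs as FASTA and GFF3
#'
#' The FASTA holds each design's reference sequence; the GFF3 annotates the
#' spacer/modifier/terminator parts and a `valve` feature spanning from the
#' valve start to the last terminator base (1-based inclusive, standard
#' GFF3).
#'
#' @param designs list of `valve_design` objects.
#' @param fasta_path,gff_path output file paths.
#' @return Invisibly, the two paths.
#' @export
write_designs <- function(designs, fasta_path, gff_path) {
  seqs <- Biostrings::DNAStringSet(vapply(designs, `[[`, character(1), "sequence"))
  names(seqs) <- vapply(designs, `[[`, character(1), "id")
  Biostrings::writeXStringSet(seqs, fasta_path)

  feats <- do.call(rbind, lapply(designs, function(d) {
    rbind(
      data.frame(seqnames = d$id, start = d$intervals$start,
                 end = d$intervals$end, type = d$intervals$role,
                 ID = d$intervals$part_id),
      data.frame(seqnames = d$id, start = d$x_s, end = d$x_e - 1L,
                 type = "valve", ID = paste0(d$id, ":valve"))
    )
  }))
  gr <- GenomicRanges::GRanges(
    seqnames = feats$seqnames,
    ranges = IRanges::IRanges(feats$start, feats$end),
    strand = "+", type = feats$type, ID = feats$ID,
    source = "valveseq"
  )
  rtracklayer::export.gff3(gr, gff_path)
  invisible(c(fasta_path, gff_path))
}

#' Read designs back from FASTA + GFF3
#'
#' Reconstructs `valve_design` objects written by [write_designs()].
#'
#' @param fasta_path,gff_path files produced by [write_designs()].
#' @return Named list of `valve_design` objects.
#' @export
read_designs <- function(fasta_path, gff_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  gff <- rtracklayer::import(gff_path)
  out <- lapply(names(seqs), function(id) {
    g <- gff[as.character(GenomicRanges::seqnames(gff)) == id]
    parts <- g[g$type != "valve"]
    valve <- g[g$type == "valve"]
    iv <- data.frame(part_id = parts$ID, role = as.character(parts$type),
                     start = GenomicRanges::start(parts),
                     end = GenomicRanges::end(parts))
    iv <- iv[order(iv$start), ]
    pid <- function(role) {
      i <- which(iv$role == role)
      if (length(i)) iv$part_id[i] else NA_character_
    }
    term <- iv[iv$role == "terminator", ]
    structure(list(
      id = id, spacer_id = pid("spacer"), modifier_id = pid("modifier"),
      terminator_id = pid("terminator"),
      sequence = as.character(seqs[[id]]), intervals = iv,
      x_s = as.integer(GenomicRanges::start(valve)),
      x_e = as.integer(GenomicRanges::end(valve)) + 1L,
      cassette_start = as.integer(min(iv$start)),
      cassette_end = as.integer(max(iv$end)),
      spacer_start = as.integer(min(iv$start)),
      terminator_start = as.integer(term$start),
      terminator_end = as.integer(term$end)
    ), class = "valve_design")
  })
  names(out) <- names(seqs)
  out
}
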