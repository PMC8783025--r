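#' Create a DNA part
#'
#' A part is one spacer, modifier, or core-terminator sequence from which
#' transcriptional-valve designs are assembled. Spacers are random
#' coding-like context sequences placed 5' of the valve; modifiers tune or
#' insulate the terminator they precede; core terminators carry the hairpin
#' and U-tract that cause intrinsic termination.
#'
#' @param id unique part identifier.
#' @param role one of `"spacer"`, `"modifier"`, `"terminator"`.
#' @param sequence DNA string (strictly A/C/G/T, nonempty).
#' @param description free-text annotation.
#' @return An object of class `valve_part`.
#' @examples
#' part("T1", "terminator", "GGCCGGTTTTTTTT")
#' @export
part <- function(id, role, sequence, description = "") {
  role <- match.arg(role, c("spacer", "modifier", "terminator"))
  assert_dna(sequence, sprintf("part '%s' sequence", id))
  if (nchar(sequence) == 0)
    stop("part '", id, "' has an empty sequence", call. = FALSE)
  structure(list(id = as.character(id), role = role, sequence = sequence,
                 description = description),
            class = "valve_part")
}

#' @export
print.valve_part <- function(x, ...) {
  cat(sprintf("<valve_part> %s [%s] %d nt\n", x$id, x$role, nchar(x$sequence)))
  invisible(x)
}

#' Group parts into a part set
#'
#' @param parts list of [part()] objects.
#' @return An object of class `part_set` with parts grouped by role.
#' @export
part_set <- function(parts) {
  stopifnot(all(vapply(parts, inherits, logical(1), "valve_part")))
  ids <- vapply(parts, `[[`, character(1), "id")
  if (anyDuplicated(ids))
    stop("part ids must be unique; duplicated: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  roles <- vapply(parts, `[[`, character(1), "role")
  ps <- list(spacer = parts[roles == "spacer"],
             modifier = parts[roles == "modifier"],
             terminator = parts[roles == "terminator"])
  if (length(ps$terminator) == 0)
    stop("no terminators", call. = FALSE)
  structure(ps, class = "part_set")
}

#' @export
print.part_set <- function(x, ...) {
  cat(sprintf("<part_set> %d spacers, %d modifiers, %d terminators\n",
              length(x$spacer), length(x$modifier), length(x$terminator)))
  invisible(x)
}

#' Generate a random spacer part
#'
#' Draws a random DNA sequence of the requested length with the last three
#' nucleotides forced to the stop codon `TAA`, mimicking coding-like context
#' sequences. The base composition target is configurable; the default is
#' uniform.
#'
#' @param length spacer length in nt (>= 3); default 33.
#' @param seed integer seed; output is bit-identical for a fixed seed.
#' @param id part id; defaults to `S<seed>`.
#' @param composition named numeric (A/C/G/T) base-composition target.
#' @return A `valve_part` of role `"spacer"` whose sequence ends in `"TAA"`.
#' @export
generate_spacer <- function(length = 33, seed = 1, id = paste0("S", seed),
                            composition = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  if (length < 3) stop("spacer length must be >= 3", call. = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(substream_seed(seed, paste0("spacer", length)))
  body <- if (length > 3) random_dna(length - 3, composition) else ""
  part(id, "spacer", paste0(body, "TAA"),
       description = sprintf("random spacer (seed %d)", as.integer(seed)))
}

#' Generate a synthetic core-terminator part
#'
#' Builds an idealized intrinsic terminator: a random hairpin stem, a loop,
#' the stem's reverse complement, and a poly-U tract (T in DNA alphabet).
#' Used to assemble synthetic libraries for simulation studies; real
#' terminator sequences can be supplied via [part()] instead.
#'
#' @param seed integer seed.
#' @param id part id; defaults to `T<seed>`.
#' @param stem_len,loop_len,u_len stem, loop and U-tract lengths in nt.
#' @return A `valve_part` of role `"terminator"`.
#' @export
generate_terminator <- function(seed = 1, id = paste0("T", seed),
                                stem_len = 10, loop_len = 6, u_len = 8) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(substream_seed(seed, "terminator"))
  stem <- random_dna(stem_len, c(A = 0.15, C = 0.35, G = 0.35, T = 0.15))
  loop <- random_dna(loop_len)
  part(id, "terminator",
       paste0(stem, loop, rev_comp(stem), strrep("T", u_len)),
       description = sprintf("synthetic hairpin terminator (seed %d)",
                             as.integer(seed)))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

# restriction sites scanned by the padding filter (given strand only by
# default; inserts are directional)
RESTRICTION_SITES <- c(EcoRI = "GAATTC", SpeI = "ACTAGT", AatII = "GACGTC")

#' Screen a padding sequence against the library design filters
#'
#' A candidate padding/modifier filler sequence is rejected if it contains
#' (a) a homopolymer run of four or more identical nucleotides, (b) a
#' recognition site for EcoRI (GAATTC), SpeI (ACTAGT) or AatII (GACGTC), or
#' (c) a predicted hairpin under a self-contained surrogate structure test:
#' two disjoint reverse-complementary segments of at least `stem_len` nt
#' separated by at least `min_loop` nt.
#'
#' @param seq DNA string.
#' @param stem_len minimum self-complementary stem length (default 4).
#' @param min_loop minimum separation between the two stem arms (default 3).
#' @param scan_revcomp also scan the reverse strand for restriction sites
#'   (default `FALSE`).
#' @return A list with elements `pass` (logical) and `reasons` (character
#'   vector, empty when `pass` is `TRUE`; values among `"homopolymer"`,
#'   `"restriction site"`, `"hairpin"`).
#' @export
passes_padding_filters <- function(seq, stem_len = 4, min_loop = 3,
                                   scan_revcomp = FALSE) {
  assert_dna(seq)
  reasons <- character(0)
  if (grepl("A{4,}|C{4,}|G{4,}|T{4,}", seq))
    reasons <- c(reasons, "homopolymer")
  targets <- if (scan_revcomp) c(seq, rev_comp(seq)) else seq
  if (any(vapply(RESTRICTION_SITES,
                 function(s) any(grepl(s, targets, fixed = TRUE)),
                 logical(1))))
    reasons <- c(reasons, "restriction site")
  if (has_hairpin(seq, stem_len, min_loop))
    reasons <- c(reasons, "hairpin")
  list(pass = length(reasons) == 0, reasons = reasons)
}

# surrogate structure test: any stem_len-mer whose reverse complement occurs
# downstream with >= min_loop nt between the two arms
#' @noRd
has_hairpin <- function(seq, stem_len = 4, min_loop = 3) {
  n <- nchar(seq)
  if (n < 2 * stem_len + min_loop) return(FALSE)
  for (i in seq_len(n - 2 * stem_len - min_loop + 1)) {
    arm <- substr(seq, i, i + stem_len - 1)
    rest_start <- i + stem_len + min_loop
    rest <- substr(seq, rest_start, n)
    if (grepl(rev_comp(arm), rest, fixed = TRUE)) return(TRUE)
  }
  FALSE
}

#' Generate a padding sequence by rejection sampling
#'
#' Draws uniform-random DNA until a draw satisfies
#' [passes_padding_filters()]; reproducible under a fixed seed.
#'
#' @param length sequence length (>= 1).
#' @param seed integer seed.
#' @param max_attempts rejection-sampling budget.
#' @inheritParams passes_padding_filters
#' @return A DNA string of the requested length that passes all filters.
#' @export
generate_padding <- function(length, seed = 1, max_attempts = 10000,
                             stem_len = 4, min_loop = 3) {
  if (length < 1) stop("padding length must be >= 1", call. = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(substream_seed(seed, paste0("padding", length)))
  for (i in seq_len(max_attempts)) {
    cand <- random_dna(length)
    if (passes_padding_filters(cand, stem_len, min_loop)$pass) return(cand)
  }
  stop("no passing padding sequence found in ", max_attempts, " attempts",
       call. = FALSE)
}

#' Read and write part sets as multi-FASTA
#'
#' Headers use the `id|role` convention.
#'
#' @param ps a `part_set`.
#' @param path FASTA file path.
#' @return `write_parts_fasta` returns `path` invisibly; `read_parts_fasta`
#'   returns a `part_set`.
#' @export
write_parts_fasta <- function(ps, path) {
  parts <- c(ps$spacer, ps$modifier, ps$terminator)
  seqs <- Biostrings::DNAStringSet(vapply(parts, `[[`, character(1), "sequence"))
  names(seqs) <- vapply(parts, function(p) paste0(p$id, "|", p$role), character(1))
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' @rdname write_parts_fasta
#' @export
read_parts_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  fields <- strsplit(names(seqs), "|", fixed = TRUE)
  parts <- lapply(seq_along(seqs), function(i) {
    if (length(fields[[i]]) < 2)
      stop("FASTA header '", names(seqs)[i], "' is not in 'id|role' form",
           call. = FALSE)
    part(fields[[i]][1], fields[[i]][2], as.character(seqs[[i]]))
  })
  part_set(parts)
}
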