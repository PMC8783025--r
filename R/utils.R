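DNA_BASES <- c("A", "C", "G", "T")

#' @noRd
assert_dna <- function(x, what = "sequence") {
  if (!is.character(x) || length(x) != 1L || is.na(x))
    stop(what, " must be a single character string", call. = FALSE)
  if (nchar(x) > 0 && grepl("[^ACGT]", x))
    stop(what, " contains non-DNA characters (alphabet is A/C/G/T)",
         call. = FALSE)
  invisible(x)
}

#' @noRd
seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

#' @noRd
rev_comp <- function(x) {
  paste(rev(seq_chars(chartr("ACGT", "TGCA", x))), collapse = "")
}

# Deterministic per-key RNG substream: a small string hash folded with the
# global seed. Keeps derived seeds in 32-bit integer range so adding designs
# to a pool never perturbs the reads of existing designs.
#' @noRd
substream_seed <- function(seed, key) {
  h <- 0
  for (c in utf8ToInt(as.character(key))) h <- (h * 131 + c) %% 2147483647
  as.integer((h + (as.numeric(seed) %% 2147483647) * 2654435) %% 2147483647)
}

#' @noRd
random_dna <- function(n, composition = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  paste(sample(DNA_BASES, n, replace = TRUE, prob = composition[DNA_BASES]),
        collapse = "")
}

#' Write a tab-separated table
#'
#' Thin wrapper around [utils::write.table()] with the conventions used by
#' all package outputs (no quoting, no row names, tab separator).
#'
#' @param x data frame.
#' @param path output file path.
#' @export
write_tsv_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
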