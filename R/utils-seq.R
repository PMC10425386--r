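#' Sequence helpers
#'
#' Small wrappers around Biostrings for plain-character DNA handling.
#' All sequences in the package are upper-case A/C/G/T character scalars;
#' base positions are 1-based and cut sites are inter-base integers (a cut
#' at `c` falls between base `c` and base `c + 1`).
#'
#' @name seq-utils
#' @keywords internal
NULL

DNA_BASES <- c("A", "C", "G", "T")

is_dna <- function(x) {
  is.character(x) && length(x) == 1L && !is.na(x) && nchar(x) > 0L &&
    grepl("^[ACGT]+$", x)
}

assert_dna <- function(x, what = "sequence") {
  if (!is_dna(x)) {
    abort(sprintf("%s must be a non-empty A/C/G/T string", what),
          class = "ampliclass_bad_sequence")
  }
  invisible(x)
}

#' Reverse complement of DNA strings
#'
#' @param x Character vector of A/C/G/T sequences.
#' @return Character vector of reverse complements.
#' @export
#' @examples
#' revcomp("ACGT")
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

complement_base <- function(x) {
  chartr("ACGT", "TGCA", x)
}

# substring of a scalar sequence; returns "" for empty ranges
seq_slice <- function(x, from, to) {
  if (to < from) return("")
  substr(x, from, to)
}

# count of occurrences of a fixed pattern in a scalar subject
count_matches <- function(pattern, subject) {
  m <- gregexpr(pattern, subject, fixed = TRUE)[[1]]
  if (length(m) == 1L && m[1] == -1L) 0L else length(m)
}

first_match <- function(pattern, subject) {
  m <- regexpr(pattern, subject, fixed = TRUE)
  if (m == -1L) NA_integer_ else as.integer(m)
}

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}
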