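#' Validate a DNA sequence
#'
#' Checks that `x` is a single non-empty string over the strict alphabet
#' A/C/G/T (degenerate IUPAC codes are rejected) and returns it uppercased.
#' All oligonucleotides in this package are stored 5'->3'.
#'
#' @param x A character scalar.
#' @param what Label used in error messages.
#' @return The validated, uppercased sequence string.
#' @export
as_dna <- function(x, what = "sequence") {
  if (!is.character(x) || length(x) != 1L || is.na(x)) {
    rlang::abort(sprintf("%s must be a single character string", what))
  }
  x <- toupper(x)
  if (nchar(x) == 0L) {
    rlang::abort(sprintf("%s must be non-empty", what))
  }
  if (grepl("[^ACGT]", x)) {
    bad <- unique(strsplit(gsub("[ACGT]", "", x), "")[[1]])
    rlang::abort(sprintf(
      "%s contains non-ACGT characters: %s", what,
      paste(bad, collapse = ", ")
    ))
  }
  x
}

#' Reverse complement of a DNA string
#'
#' @param x DNA string, 5'->3'.
#' @return The reverse complement, 5'->3'.
#' @export
#' @examples
#' reverse_complement("ACCGT")
reverse_complement <- function(x) {
  x <- as_dna(x)
  chartr(
    "ACGT", "TGCA",
    paste(rev(strsplit(x, "", fixed = TRUE)[[1]]), collapse = "")
  )
}

#' Watson-Crick complement, base by base (no reversal)
#' @noRd
wc_complement <- function(x) chartr("ACGT", "TGCA", x)

# Character vector of bases, exposed for the enumeration internals.
#' @noRd
dna_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

#' GC fraction of a DNA string
#' @param x DNA string.
#' @return Fraction of G/C bases in `[0, 1]`.
#' @export
gc_fraction <- function(x) {
  b <- dna_chars(as_dna(x))
  mean(b %in% c("G", "C"))
}

#' Longest homopolymer run length
#' @param x DNA string.
#' @return Length in nt of the longest single-base run.
#' @export
max_homopolymer_run <- function(x) {
  max(rle(dna_chars(as_dna(x)))$lengths)
}
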