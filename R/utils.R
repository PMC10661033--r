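# Internal string/sequence helpers. Sequences are plain uppercase character
# scalars; positions are 1-based inclusive throughout the package.

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse-complement DNA sequences
#'
#' @param x Character vector of DNA sequences (A/C/G/T/N).
#' @return Character vector of the same length.
#' @export
#' @examples
#' revcomp("ACGTT")
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# sequence string -> integer codes (utf8), vectorised over one string
seq_ints <- function(x) utf8ToInt(x)

# split a sequence string into single characters
seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

assert_scalar_seq <- function(x, arg = "sequence") {
  if (!is.character(x) || length(x) != 1L || is.na(x) || nchar(x) == 0L) {
    abort(sprintf("`%s` must be a single non-empty DNA string.", arg))
  }
  invisible(x)
}

assert_dna_alphabet <- function(x, arg = "sequence", allow_n = FALSE) {
  pat <- if (allow_n) "^[ACGTN]+$" else "^[ACGT]+$"
  bad <- !grepl(pat, x)
  if (any(bad)) {
    abort(sprintf("`%s` contains characters outside %s.",
                  arg, if (allow_n) "A/C/G/T/N" else "A/C/G/T"))
  }
  invisible(x)
}

is_prob <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x <= 1

# draw one alternative base per event given a reference base and a spectrum row
draw_alt_bases <- function(ref_base, n, spectrum) {
  if (n == 0L) return(character(0))
  probs <- spectrum[ref_base, ]
  sample(colnames(spectrum), size = n, replace = TRUE, prob = probs)
}
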