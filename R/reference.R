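#' Construct a reference amplicon
#'
#' A reference amplicon is the fixed DNA sequence against which mutations are
#' called. It is stored in coding-strand orientation and may carry an open
#' reading frame offset, named anchor positions (for example the first base of
#' a codon of interest) and named feature intervals (for example antibody
#' CDRs). All positions are 1-based inclusive.
#'
#' @param sequence Single uppercase DNA string (A/C/G/T only).
#' @param id Reference identifier used in FASTA/SAM output.
#' @param orf_start 1-based position of the first base of the reading frame,
#'   or `NULL` when no ORF is annotated.
#' @param anchors Named integer vector of 1-based anchor positions (e.g.
#'   `c(S65 = 193)` for the first base of codon 65), or `NULL`.
#' @param features Tibble with columns `label`, `start`, `end` (1-based,
#'   inclusive), or `NULL`.
#' @return An object of class `reference_amplicon`.
#' @export
#' @examples
#' ref <- reference_amplicon("ATGGCTAGCTAA", id = "demo", orf_start = 1)
reference_amplicon <- function(sequence, id = "amplicon", orf_start = NULL,
                               anchors = NULL, features = NULL) {
  assert_scalar_seq(sequence)
  sequence <- toupper(sequence)
  assert_dna_alphabet(sequence)
  len <- nchar(sequence)
  if (!is.null(orf_start)) {
    orf_start <- as.integer(orf_start)
    if (orf_start < 1L || orf_start > len) abort("`orf_start` outside the reference.")
  }
  if (!is.null(anchors)) {
    anchors <- setNames(as.integer(anchors), names(anchors))
    if (is.null(names(anchors)) || any(!nzchar(names(anchors)))) {
      abort("`anchors` must be a named integer vector.")
    }
    if (any(anchors < 1L | anchors > len)) abort("anchor positions outside the reference.")
  }
  if (!is.null(features)) {
    features <- as_tibble(features)
    stopifnot(all(c("label", "start", "end") %in% names(features)))
    if (any(features$start < 1L | features$end > len | features$start > features$end)) {
      abort("feature intervals outside the reference.")
    }
  }
  structure(
    list(id = id, sequence = sequence, length = len,
         orf_start = orf_start, anchors = anchors, features = features),
    class = "reference_amplicon"
  )
}

#' @export
print.reference_amplicon <- function(x, ...) {
  cat(sprintf("<reference_amplicon> %s: %d bp, GC %.1f%%\n",
              x$id, x$length, 100 * gc_content(x$sequence)))
  if (!is.null(x$orf_start)) cat(sprintf("  ORF starts at %d\n", x$orf_start))
  if (!is.null(x$anchors)) {
    cat("  anchors:", paste(sprintf("%s=%d", names(x$anchors), x$anchors), collapse = ", "), "\n")
  }
  if (!is.null(x$features)) cat(sprintf("  %d feature interval(s)\n", nrow(x$features)))
  invisible(x)
}

as_reference <- function(x) {
  if (inherits(x, "reference_amplicon")) return(x)
  if (is.character(x) && length(x) == 1L) return(reference_amplicon(x))
  abort("expected a `reference_amplicon` or a single DNA string.")
}

#' GC content of a sequence
#'
#' Fraction of G and C bases: (#G + #C) / length.
#'
#' @param seq DNA string (or character vector of them).
#' @return Numeric vector of fractions in \[0, 1\].
#' @export
#' @examples
#' gc_content("ATGC")  # 0.5
gc_content <- function(seq) {
  if (length(seq) == 0L || any(!nzchar(seq)) || any(is.na(seq))) {
    abort("`seq` must be non-empty.")
  }
  gc <- stringr::str_count(seq, "[GCgc]")
  gc / nchar(seq)
}

#' Generate a random amplicon sequence
#'
#' Draws an i.i.d. sequence at a chosen GC content, optionally forcing a
#' coding-strand NGG PAM so that a guide can be placed at a known position
#' (the two G bases are written at `pam3_pos - 1` and `pam3_pos`, which
#' requires at least 20 bp of protospacer room upstream). Uses the current
#' RNG stream; call `set.seed()` first for reproducibility.
#'
#' @param length Amplicon length in bp.
#' @param gc Target GC fraction.
#' @param pam3_pos Optional 1-based position for the 3'-most base of a forced
#'   coding-strand NGG.
#' @param id Reference identifier.
#' @inheritParams reference_amplicon
#' @return A `reference_amplicon`.
#' @export
random_amplicon <- function(length, gc = 0.45, pam3_pos = NULL, id = "sim_amplicon",
                            orf_start = NULL, anchors = NULL, features = NULL) {
  stopifnot(length >= 1)
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  chars <- sample(DNA_BASES, size = length, replace = TRUE, prob = p)
  if (!is.null(pam3_pos)) {
    pam3_pos <- as.integer(pam3_pos)
    if (pam3_pos < 23L || pam3_pos > length) {
      abort("`pam3_pos` must leave room for a 20-nt protospacer and lie inside the amplicon.")
    }
    chars[c(pam3_pos - 1L, pam3_pos)] <- "G"
  }
  reference_amplicon(paste(chars, collapse = ""), id = id, orf_start = orf_start,
                     anchors = anchors, features = features)
}

#' Read and write reference FASTA
#'
#' Thin wrappers over [Biostrings::readDNAStringSet()] /
#' [Biostrings::writeXStringSet()]. `read_reference_fasta()` returns the first
#' record as a `reference_amplicon`.
#'
#' @param ref A `reference_amplicon`.
#' @param path File path.
#' @return `write_reference_fasta()` returns `path` invisibly;
#'   `read_reference_fasta()` returns a `reference_amplicon`.
#' @export
write_reference_fasta <- function(ref, path) {
  ref <- as_reference(ref)
  x <- Biostrings::DNAStringSet(setNames(ref$sequence, ref$id))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @rdname write_reference_fasta
#' @export
read_reference_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  if (length(x) == 0L) abort("empty FASTA.")
  reference_amplicon(as.character(x[[1]]), id = names(x)[1])
}

#' Read and write BED-like feature intervals
#'
#' Features travel as BED-like three-column text (label in column 4): on disk
#' intervals are 0-based half-open as in BED; in memory they are 1-based
#' inclusive tibbles (`label`, `start`, `end`).
#'
#' @param path File path.
#' @param features Tibble with `label`, `start`, `end` (1-based inclusive).
#' @param chrom Chromosome/reference name written to column 1.
#' @return `read_features()` returns a tibble; `write_features()` returns
#'   `path` invisibly.
#' @export
read_features <- function(path) {
  x <- readr::read_tsv(path, col_names = c("chrom", "start", "end", "label"),
                       col_types = "ciic", progress = FALSE)
  tibble(label = x$label, start = x$start + 1L, end = x$end)
}

#' @rdname read_features
#' @export
write_features <- function(features, path, chrom = "amplicon") {
  out <- tibble(chrom = chrom,
                start = as.integer(features$start) - 1L,
                end = as.integer(features$end),
                label = features$label)
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}
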