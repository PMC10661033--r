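# SAM MD:Z tag handling. The MD grammar is
#   [0-9]+ ( ( [A-Z] | \^[A-Z]+ ) [0-9]+ )*
# where bare letters are reference bases at substitutions and ^-prefixed
# runs are deleted reference bases. The tag spans the reference-consuming
# part of the CIGAR (M/D/=/X, not I or soft clips).

# split a CIGAR string into a tibble of op/length
parse_cigar <- function(cigar) {
  m <- stringr::str_match_all(cigar, "(\\d+)([MIDNSHP=X])")[[1]]
  if (nrow(m) == 0L || paste0(m[, 1], collapse = "") != cigar) {
    abort(sprintf("malformed CIGAR: %s", cigar))
  }
  tibble(length = as.integer(m[, 2]), op = m[, 3])
}

cigar_ref_span <- function(cigar) {
  ops <- parse_cigar(cigar)
  sum(ops$length[ops$op %in% c("M", "D", "N", "=", "X")])
}

cigar_query_span <- function(cigar) {
  ops <- parse_cigar(cigar)
  sum(ops$length[ops$op %in% c("M", "I", "S", "=", "X")])
}

# tokenize an MD string; errors name the character offset of the problem
md_tokens <- function(md) {
  toks <- stringr::str_match_all(md, "(\\d+)|(\\^[A-Z]+)|([A-Z])")[[1]][, 1]
  if (paste0(toks, collapse = "") != md) {
    consumed <- 0L
    for (t in toks) {
      if (substr(md, consumed + 1L, consumed + nchar(t)) != t) break
      consumed <- consumed + nchar(t)
    }
    abort(sprintf("malformed MD tag at offset %d: %s", consumed + 1L, md))
  }
  toks
}

#' Parse a SAM MD tag
#'
#' Counts single-base mismatch letters outside `^`-prefixed deletion runs and
#' the total deleted length, checking the tag against the CIGAR (the MD-
#' described reference span must equal the CIGAR's M/D span).
#'
#' @param md MD tag string (without the `MD:Z:` prefix).
#' @param cigar CIGAR string of the same record.
#' @return One-row tibble with `substitution_count` and `deletion_length`.
#' @export
#' @examples
#' parse_md("10A239", "250M")      # one substitution
#' parse_md("5^AC3T1", "5M2D5M")   # one substitution, two deleted bases
parse_md <- function(md, cigar) {
  toks <- md_tokens(md)
  subs <- 0L
  dels <- 0L
  span <- 0L
  for (t in toks) {
    if (grepl("^\\d+$", t)) {
      span <- span + as.integer(t)
    } else if (startsWith(t, "^")) {
      dels <- dels + nchar(t) - 1L
      span <- span + nchar(t) - 1L
    } else {
      subs <- subs + 1L
      span <- span + 1L
    }
  }
  expected <- cigar_ref_span(cigar)
  if (span != expected) {
    abort(sprintf("MD tag spans %d reference bases but CIGAR %s spans %d.",
                  span, cigar, expected))
  }
  tibble(substitution_count = subs, deletion_length = dels)
}

# reconstruct per-reference-position mismatches from MD + CIGAR + SEQ;
# returns tibble(pos, ref, alt) with pos 1-based on the reference
md_to_mismatches <- function(md, cigar, ref_start, seq) {
  toks <- md_tokens(md)
  ops <- parse_cigar(cigar)
  # query offsets of reference-consuming columns, in reference order
  qoff <- integer(0)
  q <- 0L
  for (j in seq_len(nrow(ops))) {
    op <- ops$op[j]; len <- ops$length[j]
    if (op %in% c("M", "=", "X")) {
      qoff <- c(qoff, q + seq_len(len))
      q <- q + len
    } else if (op %in% c("I", "S")) {
      q <- q + len
    } else if (op %in% c("D", "N")) {
      qoff <- c(qoff, rep(NA_integer_, len))
    }
  }
  pos <- integer(0); refb <- character(0); altb <- character(0)
  cursor <- 0L  # index into reference-consuming columns
  for (t in toks) {
    if (grepl("^\\d+$", t)) {
      cursor <- cursor + as.integer(t)
    } else if (startsWith(t, "^")) {
      cursor <- cursor + nchar(t) - 1L
    } else {
      cursor <- cursor + 1L
      pos <- c(pos, ref_start + cursor - 1L)
      refb <- c(refb, t)
      altb <- c(altb, substr(seq, qoff[cursor], qoff[cursor]))
    }
  }
  keep <- altb != "N"
  tibble(pos = pos[keep], ref = refb[keep], alt = altb[keep])
}
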