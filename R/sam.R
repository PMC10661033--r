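# Minimal SAM text I/O for single-reference amplicon alignments. Records are
# unpaired, forward-strand, mapped (FLAG 0) or unmapped (FLAG 4); CIGAR, NM
# and MD:Z are written so external tools and the MD-based per-read counter
# can consume the file. SAM POS is 1-based, matching the package convention.

#' Write alignments as SAM
#'
#' @param alignments Alignment tibble from [align_reads()].
#' @param reference A `reference_amplicon` or DNA string.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(alignments, reference, path) {
  ref <- as_reference(reference)
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", ref$id, ref$length))
  recs <- purrr::pmap_chr(
    alignments[, c("query_id", "aligned", "ref_start", "cigar", "md", "seq",
                   "mismatches")],
    function(query_id, aligned, ref_start, cigar, md, seq, mismatches) {
      if (!aligned) {
        return(paste(query_id, 4L, "*", 0L, 0L, "*", "*", 0L, 0L, seq, "*",
                     sep = "\t"))
      }
      nm <- nrow(mismatches) + {
        ops <- parse_cigar(cigar)
        sum(ops$length[ops$op %in% c("I", "D")])
      }
      paste(query_id, 0L, ref$id, ref_start, 60L, cigar, "*", 0L, 0L, seq, "*",
            sprintf("NM:i:%d", nm), sprintf("MD:Z:%s", md), sep = "\t")
    })
  writeLines(c(header, recs), path)
  invisible(path)
}

#' Read a SAM text file
#'
#' Parses mapped records (CIGAR and MD:Z required) into the package's
#' alignment-tibble shape so SAM data from external aligners can enter the
#' pileup/profiling chain. Unmapped records (FLAG 0x4) become rows with
#' `aligned = FALSE`.
#'
#' @param path File path.
#' @param reference Optional `reference_amplicon` used to fill `identity`;
#'   when absent identity is computed from the record itself.
#' @return Alignment tibble (see [align_read()]).
#' @export
read_sam <- function(path, reference = NULL) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[!startsWith(lines, "@")]
  rows <- purrr::map(lines, function(ln) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 11L) abort("truncated SAM record.")
    flag <- as.integer(f[2])
    seq <- f[10]
    if (bitwAnd(flag, 4L) > 0L || f[6] == "*") {
      return(tibble(query_id = f[1], aligned = FALSE, ref_start = NA_integer_,
                    ref_end = NA_integer_, score = NA_real_, identity = NA_real_,
                    cigar = NA_character_, md = NA_character_, seq = seq,
                    mismatches = list(empty_mismatches()),
                    indels = list(empty_indels()),
                    ambiguous = list(integer())))
    }
    pos <- as.integer(f[4])
    cigar <- f[6]
    opt <- f[-(1:11)]
    mdf <- opt[startsWith(opt, "MD:Z:")]
    if (length(mdf) == 0L) abort(sprintf("record %s lacks an MD:Z tag.", f[1]))
    md <- sub("^MD:Z:", "", mdf[1])
    qlen <- cigar_query_span(cigar)
    if (seq != "*" && nchar(seq) != qlen) {
      abort(sprintf("record %s: SEQ length %d disagrees with CIGAR %s.",
                    f[1], nchar(seq), cigar))
    }
    mism <- md_to_mismatches(md, cigar, pos, seq)
    ops <- parse_cigar(cigar)
    # indel list from the CIGAR, insertion anchored left of the gap
    indels <- empty_indels()
    if (any(ops$op %in% c("I", "D"))) {
      rows <- list()
      rpos <- pos
      for (j in seq_len(nrow(ops))) {
        op <- ops$op[j]; len <- ops$length[j]
        if (op == "D") {
          rows[[length(rows) + 1L]] <- tibble(pos = rpos, kind = "deletion",
                                              length = len)
        } else if (op == "I") {
          rows[[length(rows) + 1L]] <- tibble(pos = rpos - 1L, kind = "insertion",
                                              length = len)
        }
        if (op %in% c("M", "D", "N", "=", "X")) rpos <- rpos + len
      }
      indels <- bind_rows(rows)
    }
    span <- cigar_ref_span(cigar)
    ncols <- span + sum(ops$length[ops$op == "I"])
    n_amb <- if (seq == "*") 0L else stringr::str_count(seq, "N")
    ident <- (ncols - nrow(mism) - sum(ops$length[ops$op %in% c("I", "D")]) -
                n_amb) / ncols
    tibble(query_id = f[1], aligned = TRUE, ref_start = pos,
           ref_end = pos + span - 1L, score = NA_real_, identity = ident,
           cigar = cigar, md = md, seq = seq,
           mismatches = list(mism), indels = list(indels),
           ambiguous = list(integer()))
  })
  bind_rows(rows)
}
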