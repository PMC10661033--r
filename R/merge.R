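# Paired-read merging by exhaustive overlap scan. Read 2 is stored 5'->3' on
# the opposite strand and is reverse-complemented before the overlap search.
# Among overlap lengths o in [min_overlap, min(L1, L2)] whose mismatch
# fraction is <= max_mismatch_frac, the one maximizing the number of matching
# bases (o - mismatches) is chosen, ties going to the longer overlap. At
# overlap mismatches the consensus takes the base with the higher quality
# (read 1 on a quality tie); consensus quality is the per-position maximum
# where the reads agree and the minimum where they disagree.

#' Merge one read pair
#'
#' @param read1,qual1 Read 1 sequence and Phred+33 quality.
#' @param read2,qual2 Read 2 (mate, opposite strand) and quality.
#' @param min_overlap Minimum admissible overlap, bp.
#' @param max_mismatch_frac Maximum mismatch fraction within the overlap.
#' @return One-row tibble with `seq`, `qual`, `merged`; when no admissible
#'   overlap exists `merged` is `FALSE` and `seq`/`qual` are `NA` (an
#'   unmerged marker, not an error).
#' @export
#' @examples
#' merge_pairs("ACGTACGTAC", strrep("?", 10), revcomp("ACGTACGTAC"),
#'             strrep("?", 10), min_overlap = 5)
merge_pairs <- function(read1, qual1, read2, qual2,
                        min_overlap = 20L, max_mismatch_frac = 0.1) {
  rs <- tibble(id = "pair", genome = NA_integer_, read1 = read1, qual1 = qual1,
               read2 = read2, qual2 = qual2)
  out <- merge_read_pairs(rs, min_overlap = min_overlap,
                          max_mismatch_frac = max_mismatch_frac)
  out[, c("seq", "qual", "merged")]
}

#' Merge all pairs of a read set
#'
#' Vectorised merging of a paired read-set tibble; unmerged pairs are kept as
#' rows with `merged = FALSE` (and are counted, not analysed, downstream).
#'
#' @param reads Paired read-set tibble (`read1`, `qual1`, `read2`, `qual2`).
#' @inheritParams merge_pairs
#' @return Tibble with `id`, `genome`, `seq`, `qual`, `merged`, `overlap`.
#' @export
merge_read_pairs <- function(reads, min_overlap = 20L, max_mismatch_frac = 0.1) {
  stopifnot(all(c("read1", "qual1", "read2", "qual2") %in% names(reads)))
  min_overlap <- as.integer(min_overlap)
  stopifnot(min_overlap >= 1L, max_mismatch_frac >= 0, max_mismatch_frac <= 1)
  n <- nrow(reads)
  out <- tibble(id = reads$id,
                genome = if ("genome" %in% names(reads)) reads$genome else NA_integer_,
                seq = NA_character_, qual = NA_character_,
                merged = FALSE, overlap = NA_integer_)
  if (n == 0L) return(out)

  rc2 <- revcomp(reads$read2)
  q2r <- vapply(reads$qual2, function(q) {
    paste(rev(seq_chars(q)), collapse = "")
  }, character(1), USE.NAMES = FALSE)

  grp <- paste(nchar(reads$read1), nchar(reads$read2))
  for (g in unique(grp)) {
    sel <- which(grp == g)
    L1 <- nchar(reads$read1[sel[1]]); L2 <- nchar(reads$read2[sel[1]])
    omax <- min(L1, L2)
    if (omax < min_overlap) next
    A <- t(vapply(reads$read1[sel], seq_ints, integer(L1), USE.NAMES = FALSE))
    B <- t(vapply(rc2[sel], seq_ints, integer(L2), USE.NAMES = FALSE))
    best_o <- rep(NA_integer_, length(sel))
    best_match <- rep(-1L, length(sel))
    for (o in seq(omax, min_overlap)) {
      # all candidates below o can yield at most o - 1 matches
      if (all(best_match >= o)) break
      mm <- if (length(sel) == 1L) {
        sum(A[1, (L1 - o + 1L):L1] != B[1, 1:o])
      } else {
        rowSums(A[, (L1 - o + 1L):L1, drop = FALSE] != B[, 1:o, drop = FALSE])
      }
      ok <- mm / o <= max_mismatch_frac
      better <- ok & (o - mm) > best_match
      if (any(better)) {
        best_o[better] <- o
        best_match[better] <- as.integer(o - mm[better])
      }
    }
    for (k in seq_along(sel)) {
      o <- best_o[k]
      if (is.na(o)) next
      i <- sel[k]
      merged <- merge_consensus(reads$read1[i], reads$qual1[i],
                                rc2[i], q2r[i], o)
      out$seq[i] <- merged$seq
      out$qual[i] <- merged$qual
      out$merged[i] <- TRUE
      out$overlap[i] <- o
    }
  }
  out
}

# build the merged sequence/quality for one pair at overlap o; r2 already
# reverse-complemented, q2 already reversed
merge_consensus <- function(r1, q1, r2, q2, o) {
  L1 <- nchar(r1); L2 <- nchar(r2)
  s1 <- seq_chars(r1); s2 <- seq_chars(r2)
  c1 <- seq_chars(q1); c2 <- seq_chars(q2)
  i1 <- (L1 - o + 1L):L1
  i2 <- 1L:o
  b1 <- s1[i1]; b2 <- s2[i2]
  p1 <- utf8ToInt(q1)[i1]; p2 <- utf8ToInt(q2)[i2]
  agree <- b1 == b2
  cons <- if_else(agree | p1 >= p2, b1, b2)
  qcons <- if_else(agree, pmax(p1, p2), pmin(p1, p2))
  seq <- paste(c(s1[seq_len(L1 - o)], cons, s2[seq(o + 1L, length.out = L2 - o)]),
               collapse = "")
  qual <- intToUtf8(c(utf8ToInt(q1)[seq_len(L1 - o)], qcons,
                      utf8ToInt(q2)[seq(o + 1L, length.out = L2 - o)]))
  list(seq = seq, qual = qual)
}
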