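# Glocal alignment of merged amplicon reads: the read aligns globally, the
# reference locally, under an affine scheme (defaults match +1, mismatch -1,
# gap open -4, gap extend -1; a gap of length L costs open + L * extend).
# Backed by Biostrings::pairwiseAlignment(type = "global-local"). For
# equal-length reads a gap-free comparison with <= 3 mismatches is provably
# optimal under the default scoring (any gapped alternative pays at least
# 2 * (open + extend) - 1 more than it can recoup), so such reads skip the
# dynamic program; tests cross-check both routes against a brute-force DP.

default_scoring <- function() c(match = 1, mismatch = -1, gap_open = -4, gap_extend = -1)

scoring_matrix <- function(scoring) {
  bases <- c(DNA_BASES, "N")
  m <- matrix(scoring[["mismatch"]], 5, 5, dimnames = list(bases, bases))
  diag(m) <- scoring[["match"]]
  m["N", ] <- 0
  m[, "N"] <- 0
  m
}

empty_mismatches <- function() tibble(pos = integer(), ref = character(), alt = character())
empty_indels <- function() tibble(pos = integer(), kind = character(), length = integer())

#' Align a read to the reference
#'
#' Optimal glocal alignment (read global, reference local) with affine gap
#' penalties; reads whose alignment identity falls below `min_identity` are
#' flagged unaligned (a value, not an error). Positions are 1-based on the
#' reference; insertions are assigned to the reference column immediately
#' left of the inserted bases.
#'
#' @param seq Read sequence (A/C/G/T/N; N columns score 0 and are excluded
#'   from pileup tallies).
#' @param reference A `reference_amplicon` or DNA string.
#' @param scoring Named numeric vector `match`, `mismatch`, `gap_open`,
#'   `gap_extend` (penalties negative).
#' @param min_identity Minimum fraction of matching columns.
#' @param id Query identifier.
#' @return One-row alignment tibble: `query_id`, `aligned`, `ref_start`,
#'   `ref_end`, `score`, `identity`, `cigar`, `md`, `seq`, plus list-columns
#'   `mismatches` (tibbles `pos`, `ref`, `alt`), `indels` (tibbles `pos`,
#'   `kind`, `length`) and `ambiguous` (integer positions of N columns).
#' @export
align_read <- function(seq, reference, scoring = default_scoring(),
                       min_identity = 0.8, id = "read") {
  out <- align_reads(tibble(id = id, seq = seq), reference,
                     scoring = scoring, min_identity = min_identity)
  out
}

#' Align a whole read set
#'
#' Vectorised form of [align_read()]: takes merged reads (a tibble with
#' `seq`, or the output of [merge_read_pairs()], whose unmerged rows are
#' dropped with a message) and returns one alignment row per read.
#'
#' @param reads Tibble with columns `id` and `seq` (optionally `merged`).
#' @inheritParams align_read
#' @return Alignment tibble, one row per read (see [align_read()]).
#' @export
align_reads <- function(reads, reference, scoring = default_scoring(),
                        min_identity = 0.8) {
  ref <- as_reference(reference)
  if (is.character(reads)) reads <- tibble(id = sprintf("read%06d", seq_along(reads)),
                                           seq = reads)
  if ("merged" %in% names(reads)) {
    n_un <- sum(!reads$merged)
    if (n_un > 0L) message(sprintf("dropping %d unmerged pair(s).", n_un))
    reads <- reads[reads$merged, ]
  }
  stopifnot(all(c("id", "seq") %in% names(reads)))
  if (any(!nzchar(reads$seq)) || any(is.na(reads$seq))) abort("empty read sequence.")
  assert_dna_alphabet(reads$seq, "reads$seq", allow_n = TRUE)
  n <- nrow(reads)

  # fast path: equal length, gap-free mismatches <= 3, default scoring; the
  # whole batch is handled with one character-code matrix
  fast <- rep(FALSE, n)
  fast_tbl <- NULL
  if (n > 0L && identical(unname(scoring), unname(default_scoring()))) {
    eq <- which(nchar(reads$seq) == ref$length)
    if (length(eq)) {
      L <- ref$length
      refi <- seq_ints(ref$sequence)
      ref_chars <- seq_chars(ref$sequence)
      Ncode <- utf8ToInt("N")
      M <- matrix(vapply(reads$seq[eq], seq_ints, integer(L),
                         USE.NAMES = FALSE), nrow = L)
      is_n <- M == Ncode
      neq <- (M != refi) & !is_n
      k <- .colSums(neq, L, length(eq))
      n_amb <- .colSums(is_n, L, length(eq))
      keep <- k <= 3L
      fast[eq[keep]] <- TRUE
      if (any(keep)) {
        cols <- which(keep)
        kk <- k[cols]; aa <- n_amb[cols]
        score <- (L - kk - aa) * scoring[["match"]] + kk * scoring[["mismatch"]]
        identity <- (L - kk - aa) / L
        # mismatch list-column, built from one arr.ind table
        mm_list <- rep(list(empty_mismatches()), length(cols))
        md <- rep(as.character(L), length(cols))
        hit <- which(neq[, cols, drop = FALSE], arr.ind = TRUE)
        if (nrow(hit)) {
          mm_all <- tibble(col = hit[, 2], pos = as.integer(hit[, 1]),
                           ref = ref_chars[hit[, 1]],
                           alt = substr(reads$seq[eq[cols]][hit[, 2]],
                                        hit[, 1], hit[, 1]))
          mm_all <- arrange(mm_all, .data$col, .data$pos)
          grp <- split(seq_len(nrow(mm_all)), mm_all$col)
          for (gname in names(grp)) {
            gi <- grp[[gname]]
            j <- as.integer(gname)
            mm_list[[j]] <- tibble(pos = mm_all$pos[gi], ref = mm_all$ref[gi],
                                   alt = mm_all$alt[gi])
            md[j] <- md_from_mismatches(L, mm_list[[j]])
          }
        }
        amb_list <- rep(list(integer(0)), length(cols))
        if (any(aa > 0)) {
          nh <- which(is_n[, cols, drop = FALSE], arr.ind = TRUE)
          for (j in unique(nh[, 2])) {
            amb_list[[j]] <- as.integer(nh[nh[, 2] == j, 1])
          }
        }
        fast_tbl <- tibble(
          query_id = reads$id[eq[cols]], aligned = identity >= min_identity,
          ref_start = 1L, ref_end = L, score = as.numeric(score),
          identity = identity, cigar = paste0(L, "M"), md = md,
          seq = reads$seq[eq[cols]], mismatches = mm_list,
          indels = rep(list(empty_indels()), length(cols)),
          ambiguous = amb_list,
          .row = eq[cols])
      }
    }
  }
  slow <- which(!fast)
  slow_rows <- vector("list", length(slow))
  if (length(slow)) {
    mat <- scoring_matrix(scoring)
    pa <- Biostrings::pairwiseAlignment(
      pattern = Biostrings::DNAStringSet(reads$seq[slow]),
      subject = Biostrings::DNAString(ref$sequence),
      type = "global-local", substitutionMatrix = mat,
      gapOpening = -scoring[["gap_open"]], gapExtension = -scoring[["gap_extend"]])
    pat_al <- as.character(Biostrings::alignedPattern(pa))
    sub_al <- as.character(Biostrings::alignedSubject(pa))
    starts <- Biostrings::start(Biostrings::subject(pa))
    scores <- Biostrings::score(pa)
    for (k in seq_along(slow)) {
      i <- slow[k]
      slow_rows[[k]] <- walk_alignment(reads$id[i], reads$seq[i], pat_al[k],
                                       sub_al[k], starts[k], scores[k],
                                       min_identity)
      slow_rows[[k]]$.row <- i
    }
  }
  out <- bind_rows(c(list(fast_tbl), slow_rows))
  out <- arrange(out, .data$.row)
  select(out, -".row")
}

# MD string for a gap-free alignment spanning ref columns 1..L
md_from_mismatches <- function(L, mism) {
  if (nrow(mism) == 0L) return(as.character(L))
  pos <- mism$pos
  runs <- diff(c(0L, pos)) - 1L
  paste0(paste0(runs, mism$ref, collapse = ""), L - pos[length(pos)])
}

# turn a pair of aligned (gapped) strings into an alignment row
walk_alignment <- function(id, seq, pat, sub, ref_start, score, min_identity) {
  p <- seq_chars(pat)
  s <- seq_chars(sub)
  ncol <- length(p)
  pgap <- p == "-"
  sgap <- s == "-"
  ref_pos <- ref_start - 1L + cumsum(!sgap)   # ref position of each column
  match_col <- !pgap & !sgap & p == s & p != "N"
  amb_col <- !pgap & !sgap & (p == "N" | s == "N")
  mm_col <- !pgap & !sgap & p != s & !amb_col
  identity <- sum(match_col) / ncol
  mism <- if (any(mm_col)) {
    tibble(pos = ref_pos[mm_col], ref = s[mm_col], alt = p[mm_col])
  } else empty_mismatches()
  # indels: runs of pattern gaps are deletions (ref consumed), runs of
  # subject gaps are insertions anchored to the column on their left
  indels <- empty_indels()
  if (any(pgap) || any(sgap)) {
    r <- rle(if_else(pgap, "D", if_else(sgap, "I", "M")))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    rows <- list()
    for (j in seq_along(r$values)) {
      if (r$values[j] == "D") {
        rows[[length(rows) + 1L]] <- tibble(pos = ref_pos[starts[j]],
                                            kind = "deletion",
                                            length = r$lengths[j])
      } else if (r$values[j] == "I") {
        left <- if (starts[j] == 1L) ref_start - 1L else ref_pos[starts[j] - 1L]
        rows[[length(rows) + 1L]] <- tibble(pos = as.integer(left),
                                            kind = "insertion",
                                            length = r$lengths[j])
      }
    }
    indels <- bind_rows(rows)
  }
  ref_end <- ref_start - 1L + sum(!sgap)
  cigar <- cigar_from_cols(pgap, sgap)
  md <- md_from_cols(p, s, pgap, sgap)
  tibble(query_id = id, aligned = identity >= min_identity,
         ref_start = as.integer(ref_start), ref_end = as.integer(ref_end),
         score = score, identity = identity, cigar = cigar, md = md, seq = seq,
         mismatches = list(mism), indels = list(indels),
         ambiguous = list(as.integer(ref_pos[amb_col])))
}

cigar_from_cols <- function(pgap, sgap) {
  ops <- if_else(pgap, "D", if_else(sgap, "I", "M"))
  r <- rle(ops)
  paste0(r$lengths, r$values, collapse = "")
}

# MD tag over the aligned columns (match runs, mismatch ref letters,
# ^-prefixed deletion runs); insertions are invisible to MD
md_from_cols <- function(p, s, pgap, sgap) {
  keep <- !sgap  # MD walks reference-consuming columns only
  p <- p[keep]; s <- s[keep]; del <- pgap[keep]
  out <- character(0)
  run <- 0L
  i <- 1L
  n <- length(p)
  while (i <= n) {
    if (del[i]) {
      out <- c(out, as.character(run), "^")
      run <- 0L
      while (i <= n && del[i]) { out <- c(out, s[i]); i <- i + 1L }
    } else if (p[i] == s[i] || p[i] == "N" || s[i] == "N") {
      run <- run + 1L; i <- i + 1L
    } else {
      out <- c(out, as.character(run), s[i])
      run <- 0L; i <- i + 1L
    }
  }
  out <- c(out, as.character(run))
  paste(out, collapse = "")
}

#' Count substitutions on an alignment
#'
#' The per-read substitution multiplicity: the number of mismatch entries of
#' an aligned read (deleted bases do not count). Errors on unaligned reads.
#'
#' @param alignments Alignment tibble (one or more rows).
#' @return Integer vector of per-read substitution counts.
#' @export
substitutions_per_read <- function(alignments) {
  if (any(!alignments$aligned)) abort("substitutions_per_read() requires aligned reads.")
  vapply(alignments$mismatches, nrow, integer(1))
}
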