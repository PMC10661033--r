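# Per-position pileup tallies. For each reference position, `depth_clean`
# counts reads covering the column through match/substitution columns only:
# a read with a deletion spanning the column, or an insertion anchored at it,
# is excluded from depth_clean (per column, not per read) and counted in
# `indel_count` instead. N columns are excluded from both numerator and
# denominator.

#' Build a pileup from alignments
#'
#' @param alignments Alignment tibble from [align_reads()]; unaligned rows
#'   are ignored.
#' @param reference A `reference_amplicon` or DNA string.
#' @return Pileup tibble: `pos`, `ref`, `depth_clean`, `A`, `C`, `G`, `T`
#'   (alternative-base counts), `indel_count`.
#' @export
build_pileup <- function(alignments, reference) {
  ref <- as_reference(reference)
  n <- ref$length
  al <- alignments[alignments$aligned, ]
  if (nrow(al) > 0 && (min(al$ref_start) < 1L || max(al$ref_end) > n)) {
    abort("alignment extends beyond the reference bounds.")
  }
  depth <- rep(0L, n)
  if (nrow(al)) {
    cov <- IRanges::coverage(IRanges::IRanges(al$ref_start, al$ref_end), width = n)
    depth <- as.integer(cov)
  }
  # per read, columns lost to indels: deletion spans plus insertion anchors
  indel_cols <- integer(0)
  if (nrow(al)) {
    per_read <- purrr::map(al$indels, function(ind) {
      if (is.null(ind) || nrow(ind) == 0L) return(integer(0))
      cols <- integer(0)
      del <- ind[ind$kind == "deletion", ]
      if (nrow(del)) {
        cols <- c(cols, unlist(purrr::map2(del$pos, del$length,
                                           function(p, l) seq(p, length.out = l))))
      }
      ins <- ind[ind$kind == "insertion", ]
      if (nrow(ins)) cols <- c(cols, ins$pos[ins$pos >= 1L])
      unique(cols)
    })
    indel_cols <- unlist(per_read)
  }
  indel_count <- tabulate(indel_cols, nbins = n)
  # N columns drop out of the denominator entirely
  amb_cols <- unlist(al$ambiguous)
  amb_count <- tabulate(amb_cols, nbins = n)
  depth_clean <- depth - indel_count - amb_count

  alt <- matrix(0L, n, 4, dimnames = list(NULL, DNA_BASES))
  mism <- bind_rows(al$mismatches)
  if (nrow(mism)) {
    tab <- count(mism, .data$pos, .data$alt)
    alt[cbind(tab$pos, match(tab$alt, DNA_BASES))] <- tab$n
  }
  tibble(pos = seq_len(n), ref = seq_chars(ref$sequence),
         depth_clean = as.integer(depth_clean),
         A = alt[, "A"], C = alt[, "C"], G = alt[, "G"], T = alt[, "T"],
         indel_count = as.integer(indel_count))
}

alt_total <- function(pileup) {
  pileup$A + pileup$C + pileup$G + pileup$T
}

#' Write and read samtools-style text pileup
#'
#' A minimal text pileup: columns chrom, pos (1-based), ref base, depth
#' (clean + indel), base string and quality string. Matches are written as
#' `.`, substitutions as the alternative base, indel-affected reads as `*`.
#' The reader also accepts lower-case (reverse-strand) base calls, `^X`/`$`
#' read start/end markers and `+N`/`-N` inline indel sequences as produced
#' by samtools, counting `+`/`-`-marked and `*` reads into `indel_count`.
#'
#' @param pileup Pileup tibble.
#' @param path File path.
#' @param chrom Reference name for column 1.
#' @return `read_pileup()` returns a pileup tibble; `write_pileup()` returns
#'   `path` invisibly.
#' @export
write_pileup <- function(pileup, path, chrom = "amplicon") {
  bases <- purrr::pmap_chr(pileup, function(pos, ref, depth_clean, A, C, G, T,
                                            indel_count, ...) {
    alts <- c(A = A, C = C, G = G, T = T)
    alts <- alts[alts > 0]
    paste0(strrep(".", depth_clean - sum(alts)),
           paste(strrep(names(alts), alts), collapse = ""),
           strrep("*", indel_count))
  })
  depth <- pileup$depth_clean + pileup$indel_count
  quals <- strrep("?", nchar(bases))
  lines <- paste(chrom, pileup$pos, pileup$ref, depth, bases, quals, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_pileup
#' @export
read_pileup <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  parts <- stringr::str_split_fixed(lines, "\t", 6)
  n <- nrow(parts)
  out <- tibble(pos = as.integer(parts[, 2]), ref = toupper(parts[, 3]),
                depth_clean = 0L, A = 0L, C = 0L, G = 0L, T = 0L,
                indel_count = 0L)
  for (i in seq_len(n)) {
    tok <- parse_pileup_bases(parts[i, 5])
    out$depth_clean[i] <- tok$clean
    out$A[i] <- tok$alt["A"]; out$C[i] <- tok$alt["C"]
    out$G[i] <- tok$alt["G"]; out$T[i] <- tok$alt["T"]
    out$indel_count[i] <- tok$indel
  }
  out
}

# tokenize one mpileup base string
parse_pileup_bases <- function(x) {
  chars <- seq_chars(x)
  alt <- c(A = 0L, C = 0L, G = 0L, T = 0L)
  clean <- 0L
  indel <- 0L
  i <- 1L
  n <- length(chars)
  last_base <- NA_character_  # ".", or an alt base, when the previous symbol was a call
  while (i <= n) {
    ch <- chars[i]
    if (ch == "^") {
      i <- i + 2L  # mapping-quality byte follows
    } else if (ch == "$") {
      i <- i + 1L
    } else if (ch %in% c("+", "-")) {
      j <- i + 1L
      while (j <= n && grepl("[0-9]", chars[j])) j <- j + 1L
      len <- as.integer(paste(chars[(i + 1L):(j - 1L)], collapse = ""))
      i <- j + len
      # the read carrying this indel is not clean at the column
      if (!is.na(last_base)) {
        clean <- clean - 1L
        indel <- indel + 1L
        if (last_base != ".") alt[last_base] <- alt[last_base] - 1L
      }
      last_base <- NA_character_
    } else if (ch %in% c(".", ",")) {
      clean <- clean + 1L; i <- i + 1L; last_base <- "."
    } else if (toupper(ch) %in% DNA_BASES) {
      alt[toupper(ch)] <- alt[toupper(ch)] + 1L
      clean <- clean + 1L; i <- i + 1L; last_base <- toupper(ch)
    } else if (ch == "*") {
      indel <- indel + 1L; i <- i + 1L; last_base <- NA_character_
    } else {
      i <- i + 1L; last_base <- NA_character_  # N or other symbols: skip
    }
  }
  list(clean = clean, alt = alt, indel = indel)
}
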