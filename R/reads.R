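# Read sampling: emulates end-anchored paired amplicon sequencing (e.g.
# PE250 MiSeq). Read 1 is the genome's first `read_length` bases on the
# coding strand; read 2 is the reverse complement of its last `read_length`
# bases, so the pair covers the amplicon from both ends and merges across
# the middle. Base qualities are constant Q30 except injected sequencing
# errors, written at Q15.

QUAL_BASE <- "?"  # Phred+33 Q30
QUAL_ERR <- "0"   # Phred+33 Q15

#' Sample sequencing reads from a genome pool
#'
#' Each read (or pair) is drawn from a uniformly chosen genome;
#' substitution-type sequencing errors are injected per base with probability
#' `seq_error_rate`. Uses its own `seed`, independent of the genome-drawing
#' stream, so changing `n_reads` never changes the pool.
#'
#' @param pool A `genome_pool`.
#' @param n_reads Number of reads (pairs when `paired`); 0 gives an empty
#'   set.
#' @param read_length Read length in bp; defaults to the pool
#'   configuration's. Must not exceed the shortest genome.
#' @param paired Paired-end flag; defaults to the pool configuration's.
#' @param seq_error_rate Per-base substitution error probability; defaults to
#'   the pool configuration's.
#' @param seed Integer seed for the read-sampling stream.
#' @return A tibble (`read_set`): columns `id`, `genome` plus either
#'   `read1`, `qual1`, `read2`, `qual2` (paired) or `seq`, `qual`.
#' @export
sample_reads <- function(pool, n_reads, read_length = NULL, paired = NULL,
                         seq_error_rate = NULL, seed = 1L) {
  stopifnot(inherits(pool, "genome_pool"))
  cfg <- pool$config
  if (is.null(read_length)) read_length <- cfg$read_length
  if (is.null(paired)) paired <- cfg$paired
  if (is.null(seq_error_rate)) seq_error_rate <- cfg$seq_error_rate
  read_length <- as.integer(read_length)
  n_reads <- as.integer(n_reads)
  stopifnot(n_reads >= 0, read_length >= 1)
  glen <- nchar(pool$sequences)
  if (read_length > min(glen)) abort("`read_length` exceeds a genome length.")
  if (n_reads == 0L) {
    if (paired) {
      return(tibble(id = character(), genome = integer(), read1 = character(),
                    qual1 = character(), read2 = character(), qual2 = character()))
    }
    return(tibble(id = character(), genome = integer(),
                  seq = character(), qual = character()))
  }
  set.seed(as.integer(seed))
  gidx <- sample.int(length(pool$sequences), n_reads, replace = TRUE)
  src <- pool$sequences[gidx]
  q0 <- strrep(QUAL_BASE, read_length)
  if (paired) {
    r1 <- substr(src, 1L, read_length)
    r2 <- revcomp(substr(src, glen[gidx] - read_length + 1L, glen[gidx]))
    r1 <- inject_errors(r1, seq_error_rate)
    r2 <- inject_errors(r2, seq_error_rate)
    tibble(id = sprintf("read%06d", seq_len(n_reads)), genome = gidx,
           read1 = r1$seq, qual1 = r1$qual %||% q0,
           read2 = r2$seq, qual2 = r2$qual %||% q0)
  } else {
    s <- substr(src, 1L, read_length)
    s <- inject_errors(s, seq_error_rate)
    tibble(id = sprintf("read%06d", seq_len(n_reads)), genome = gidx,
           seq = s$seq, qual = s$qual %||% q0)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# inject substitution sequencing errors into equal-length reads; returns
# list(seq, qual) with qual NULL when untouched (constant Q30)
inject_errors <- function(seqs, rate) {
  n <- length(seqs)
  L <- nchar(seqs[1])
  qual <- NULL
  if (rate > 0) {
    hit <- which(runif(n * L) < rate)
    if (length(hit)) {
      qual <- rep(strrep(QUAL_BASE, L), n)
      ridx <- (hit - 1L) %/% L + 1L
      pos <- (hit - 1L) %% L + 1L
      for (k in seq_along(hit)) {
        i <- ridx[k]; j <- pos[k]
        old <- substr(seqs[i], j, j)
        new <- sample(setdiff(DNA_BASES, old), 1L)
        substr(seqs[i], j, j) <- new
        substr(qual[i], j, j) <- QUAL_ERR
      }
    }
  }
  list(seq = seqs, qual = qual)
}

#' Write and read FASTQ (Phred+33)
#'
#' Paired read sets are written as two mate files `<prefix>_R1.fastq` /
#' `<prefix>_R2.fastq`; single-end sets as `<prefix>.fastq`. Reading uses
#' [Biostrings::readQualityScaledDNAStringSet()].
#'
#' @param reads A read-set tibble from [sample_reads()].
#' @param prefix Output path prefix.
#' @return `write_reads_fastq()` returns the written paths invisibly;
#'   `read_reads_fastq()` returns a read-set tibble.
#' @export
write_reads_fastq <- function(reads, prefix) {
  write_one <- function(ids, seqs, quals, path) {
    # Biostrings warns about dropping the (empty) metadata columns it added
    suppressWarnings({
      x <- Biostrings::QualityScaledDNAStringSet(
        Biostrings::DNAStringSet(setNames(seqs, ids)),
        Biostrings::PhredQuality(quals))
      Biostrings::writeQualityScaledXStringSet(x, path)
    })
  }
  if ("read1" %in% names(reads)) {
    p1 <- paste0(prefix, "_R1.fastq"); p2 <- paste0(prefix, "_R2.fastq")
    write_one(reads$id, reads$read1, reads$qual1, p1)
    write_one(reads$id, reads$read2, reads$qual2, p2)
    return(invisible(c(p1, p2)))
  }
  p <- paste0(prefix, ".fastq")
  write_one(reads$id, reads$seq, reads$qual, p)
  invisible(p)
}

#' @rdname write_reads_fastq
#' @param path1,path2 FASTQ paths; give `path2` for paired data.
#' @export
read_reads_fastq <- function(path1, path2 = NULL) {
  # the reader warns about dropped (empty) metadata columns
  r1 <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path1))
  if (is.null(path2)) {
    return(tibble(id = names(r1), genome = NA_integer_,
                  seq = unname(as.character(r1)),
                  qual = unname(as.character(Biostrings::quality(r1)))))
  }
  r2 <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path2))
  if (length(r1) != length(r2)) abort("mate FASTQ files differ in length.")
  tibble(id = names(r1), genome = NA_integer_,
         read1 = unname(as.character(r1)),
         qual1 = unname(as.character(Biostrings::quality(r1))),
         read2 = unname(as.character(r2)),
         qual2 = unname(as.character(Biostrings::quality(r2))))
}
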