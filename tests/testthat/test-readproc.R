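ref <- fixture_reference()
guide <- fixture_guide(ref)

test_that("merging reconstructs the source molecule from a clean pair", {
  # identical fully-overlapping reads
  r <- substr(ref$sequence, 1, 100)
  m <- merge_pairs(r, q30(100), revcomp(r), q30(100), min_overlap = 20)
  expect_true(m$merged)
  expect_equal(m$seq, r)
  # 250 + 250 over a 400-bp amplicon: overlap 100, merged length 400
  r1 <- substr(ref$sequence, 1, 250)
  r2 <- revcomp(substr(ref$sequence, 151, 400))
  m <- merge_pairs(r1, q30(250), r2, q30(250))
  expect_true(m$merged)
  expect_equal(nchar(m$seq), 400)
  expect_equal(m$seq, ref$sequence)
  # no admissible overlap: unmerged marker, not an error
  u <- merge_pairs(strrep("A", 50), q30(50), strrep("A", 50), q30(50),
                   min_overlap = 20, max_mismatch_frac = 0)
  expect_false(u$merged)  # revcomp makes it poly-T against poly-A
  expect_true(is.na(u$seq))
})

test_that("overlap consensus takes the higher-quality base", {
  r <- substr(ref$sequence, 101, 200)
  bad <- r
  substr(bad, 50, 50) <- setdiff(c("A", "C", "G", "T"),
                                 substr(r, 50, 50))[1]
  # read 1 carries the error at Q15, read 2 is right at Q30 -> consensus = r
  q1 <- q30(100); substr(q1, 50, 50) <- "0"
  m <- merge_pairs(bad, q1, revcomp(r), q30(100), min_overlap = 20)
  expect_true(m$merged)
  expect_equal(m$seq, r)
  # disagreement quality is the minimum of the two
  expect_equal(substr(m$qual, 50, 50), "0")
  # reversed roles: read 1 right at Q30, read 2 wrong at Q15
  q2 <- q30(100); substr(q2, 51, 51) <- "0"  # reversed coordinate of pos 50
  m2 <- merge_pairs(r, q30(100), revcomp(bad), q2, min_overlap = 20)
  expect_equal(m2$seq, r)
})

test_that("merging a merged read with itself is idempotent", {
  r1 <- substr(ref$sequence, 1, 250)
  r2 <- revcomp(substr(ref$sequence, 151, 400))
  m <- merge_pairs(r1, q30(250), r2, q30(250))
  again <- merge_pairs(m$seq, m$qual, revcomp(m$seq),
                       paste(rev(strsplit(m$qual, "")[[1]]), collapse = ""))
  expect_equal(again$seq, m$seq)
})

test_that("alignment reproduces known edits and the brute-force DP score", {
  # exact substring: no mismatches, correct placement
  al <- align_reads(substr(ref$sequence, 51, 150), ref)
  expect_true(al$aligned)
  expect_equal(al$ref_start, 51L)
  expect_equal(nrow(al$mismatches[[1]]), 0)
  expect_equal(nrow(al$indels[[1]]), 0)
  # single substitution at a known offset
  rd <- substr(ref$sequence, 51, 150)
  old <- substr(rd, 30, 30)
  substr(rd, 30, 30) <- setdiff(c("A", "C", "G", "T"), old)[1]
  al <- align_reads(rd, ref)
  mm <- al$mismatches[[1]]
  expect_equal(nrow(mm), 1)
  expect_equal(mm$pos, 80L)
  expect_equal(mm$ref, old)
  # single deleted base: one deletion op, score equals the brute-force DP
  small <- reference_amplicon(substr(ref$sequence, 1, 50))
  rd <- paste0(substr(small$sequence, 1, 19), substr(small$sequence, 21, 50))
  al <- align_reads(rd, small)
  ind <- al$indels[[1]]
  expect_equal(nrow(ind), 1)
  expect_equal(ind$kind, "deletion")
  expect_equal(ind$length, 1L)
  expect_equal(al$score, oracle_glocal_score(rd, small$sequence))
  expect_error(align_reads("", ref), "empty")
})

test_that("alignment scores match the brute-force DP on randomized reads", {
  set.seed(31)
  small <- reference_amplicon(substr(ref$sequence, 1, 50))
  for (k in 1:25) {
    rd <- random_read(small$sequence, sample(20:45, 1),
                      n_sub = sample(0:3, 1), del = runif(1) < 0.4)
    al <- align_reads(rd, small)
    expect_equal(al$score, oracle_glocal_score(rd, small$sequence))
  }
  # equal-length reads exercise the gap-free fast path; same contract
  for (k in 1:10) {
    rd <- random_read(ref$sequence, 400, n_sub = sample(0:3, 1))
    al <- align_reads(rd, ref)
    expect_equal(al$score, oracle_glocal_score(rd, ref$sequence))
    expect_equal(al$cigar, "400M")
  }
})

test_that("heavily diverged reads are flagged unaligned, not errored", {
  junk <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE), collapse = "")
  al <- align_reads(junk, ref)
  expect_false(al$aligned)
  expect_error(substitutions_per_read(al), "aligned")
})

test_that("pileup counts match direct expectations and a brute-force recount", {
  # 100 identical perfect reads
  reads <- rep(ref$sequence, 100)
  al <- align_reads(reads, ref)
  pile <- build_pileup(al, ref)
  expect_true(all(pile$depth_clean == 100))
  expect_true(all(alt_sum <- pile$A + pile$C + pile$G + pile$T) == 0)
  # 5 reads carrying the same substitution among 100
  pos17 <- which(strsplit(ref$sequence, "")[[1]] != "T")[17]
  mutated <- ref$sequence
  substr(mutated, pos17, pos17) <- "T"
  al <- align_reads(c(rep(ref$sequence, 95), rep(mutated, 5)), ref)
  pile <- build_pileup(al, ref)
  expect_equal(pile$T[pos17], 5L)
  expect_equal(pile$depth_clean[pos17], 100L)
  # randomized 200-read instance vs the per-read loop oracle
  set.seed(77)
  reads <- vapply(1:200, function(i) {
    random_read(ref$sequence, sample(150:400, 1),
                n_sub = sample(0:3, 1), del = runif(1) < 0.3)
  }, character(1))
  al <- align_reads(reads, ref)
  pile <- build_pileup(al, ref)
  orc <- oracle_pileup(al, ref)
  expect_equal(pile$depth_clean, orc$depth_clean)
  expect_equal(pile$indel_count, orc$indel_count)
  expect_equal(unname(as.matrix(pile[, c("A", "C", "G", "T")])),
               unname(orc$alt))
  expect_true(all(pile$A + pile$C + pile$G + pile$T <= pile$depth_clean))
})

test_that("N bases drop out of both numerator and denominator", {
  rd <- ref$sequence
  substr(rd, 25, 25) <- "N"
  al <- align_reads(rd, ref)
  pile <- build_pileup(al, ref)
  expect_equal(pile$depth_clean[25], 0L)
  expect_equal(sum(pile[25, c("A", "C", "G", "T")]), 0)
  expect_equal(pile$depth_clean[26], 1L)
})

test_that("substitutions_per_read counts mismatches, not deletions", {
  rd <- ref$sequence
  substr(rd, 30, 30) <- setdiff(c("A", "C", "G", "T"), substr(rd, 30, 30))[1]
  substr(rd, 60, 60) <- setdiff(c("A", "C", "G", "T"), substr(rd, 60, 60))[1]
  chars <- strsplit(rd, "")[[1]][-100]  # plus one deletion
  rd <- paste(chars, collapse = "")
  al <- align_reads(c(ref$sequence, rd), ref)
  expect_equal(substitutions_per_read(al), c(0L, 2L))
})

test_that("parse_md follows the MD grammar", {
  expect_equal(parse_md("250", "250M"),
               tibble::tibble(substitution_count = 0L, deletion_length = 0L))
  expect_equal(parse_md("10A239", "250M"),
               tibble::tibble(substitution_count = 1L, deletion_length = 0L))
  expect_equal(parse_md("5^AC3T1", "5M2D5M"),
               tibble::tibble(substitution_count = 1L, deletion_length = 2L))
  expect_error(parse_md("10A239", "200M"), "spans")
  expect_error(parse_md("10a239", "250M"), "offset")
})

test_that("MD tags on serialized SAM agree with the internal mismatch lists", {
  set.seed(13)
  pool <- simulate_mutagenesis(
    simulation_config(ref, guide, base_rate = 5e-3, generations = 20.5,
                      indel_rate = 2e-4, n_genomes = 100, seed = 21))
  reads <- sample_reads(pool, 150, seq_error_rate = 0.001, seed = 22)
  merged <- merge_read_pairs(reads)
  al <- suppressMessages(align_reads(merged, ref))
  al_ok <- al[al$aligned, ]
  sam <- tempfile(fileext = ".sam")
  write_sam(al_ok, ref, sam)
  parsed <- purrr::map2_dfr(al_ok$md, al_ok$cigar, parse_md)
  expect_equal(parsed$substitution_count, unname(substitutions_per_read(al_ok)))
  # full SAM round trip preserves placement and mismatch lists
  back <- read_sam(sam, ref)
  expect_equal(back$ref_start, al_ok$ref_start)
  expect_equal(back$cigar, al_ok$cigar)
  for (i in seq_len(nrow(back))) {
    expect_equal(back$mismatches[[i]], al_ok$mismatches[[i]])
    expect_equal(back$indels[[i]], al_ok$indels[[i]])
  }
  # and the pileup built from the SAM route matches the internal route
  expect_equal(build_pileup(back, ref), build_pileup(al_ok, ref))
})

test_that("simulated truth is recovered exactly through the pileup", {
  # each genome aligned once, no sequencing error: alt counts == truth tallies
  pool <- simulate_mutagenesis(
    simulation_config(ref, guide, base_rate = 5e-3, generations = 20.5,
                      n_genomes = 200, seed = 4))
  al <- align_reads(pool$sequences, ref)
  pile <- build_pileup(al, ref)
  truth <- dplyr::count(pool$mutations, pos, alt)
  for (i in seq_len(nrow(truth))) {
    expect_equal(pile[[truth$alt[i]]][truth$pos[i]], truth$n[i])
  }
  expect_equal(sum(pile$A + pile$C + pile$G + pile$T), nrow(pool$mutations))
})

test_that("text pileup round-trips and tolerates samtools markup", {
  pool <- simulate_mutagenesis(
    simulation_config(ref, guide, base_rate = 5e-3, generations = 20.5,
                      n_genomes = 50, seed = 6))
  al <- align_reads(pool$sequences, ref)
  pile <- build_pileup(al, ref)
  tmp <- tempfile(fileext = ".pileup")
  write_pileup(pile, tmp)
  back <- read_pileup(tmp)
  expect_equal(back, pile)
  # samtools-style decorations parse to the same counts
  lines <- c("amp\t1\tA\t5\t..,.^].\t?????",
             "amp\t2\tC\t5\t.$,TT*\t?????",
             "amp\t3\tG\t4\t..+2AT,a\t????")
  tmp2 <- tempfile(fileext = ".pileup")
  writeLines(lines, tmp2)
  p2 <- read_pileup(tmp2)
  expect_equal(p2$depth_clean, c(5L, 4L, 3L))
  expect_equal(p2$T[2], 2L)
  expect_equal(p2$indel_count, c(0L, 1L, 1L))
  expect_equal(p2$A[3], 1L)
})

test_that("FASTQ written by the simulator reads back identically", {
  pool <- simulate_mutagenesis(
    simulation_config(ref, guide, base_rate = 1e-3, n_genomes = 20, seed = 2))
  reads <- sample_reads(pool, 25, seed = 3)
  prefix <- tempfile("reads_")
  write_reads_fastq(reads, prefix)
  back <- read_reads_fastq(paste0(prefix, "_R1.fastq"), paste0(prefix, "_R2.fastq"))
  expect_equal(back$read1, reads$read1)
  expect_equal(back$read2, reads$read2)
  expect_equal(back$qual1, reads$qual1)
  expect_equal(back$id, reads$id)
})
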