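ref <- fixture_reference()
guide <- fixture_guide(ref)

pcol <- function(depth, alts = c(A = 0, C = 0, G = 0, T = 0), indel = 0,
                 refb = "C", pos = 1L) {
  tibble::tibble(pos = pos, ref = refb, depth_clean = as.integer(depth),
                 A = as.integer(alts[["A"]]), C = as.integer(alts[["C"]]),
                 G = as.integer(alts[["G"]]), T = as.integer(alts[["T"]]),
                 indel_count = as.integer(indel))
}

# a synthetic profile from explicit rates, fully covered
rate_profile <- function(rates, refs = NULL) {
  n <- length(rates)
  if (is.null(refs)) refs <- rep("C", n)
  mutation_profile(tibble::tibble(
    pos = seq_len(n), ref = refs, depth_clean = 1000L,
    A = 0L, C = 0L, G = 0L, T = as.integer(round(rates * 1000)),
    indel_count = 0L))
}

test_that("substitution rate is mismatches over clean depth", {
  expect_equal(substitution_rate(pcol(100)), 0)
  expect_equal(substitution_rate(pcol(100, c(A = 0, C = 0, G = 0, T = 5))), 0.05)
  # 100 covering reads of which 10 carry indels: denominator is 90
  col <- pcol(90, c(A = 0, C = 0, G = 0, T = 5), indel = 10)
  expect_equal(substitution_rate(col), 5 / 90)
  expect_error(substitution_rate(pcol(-1)), "negative")
  prof <- mutation_profile(pcol(0))
  expect_equal(prof$sub_rate, 0)
  expect_false(prof$covered)
})

test_that("background subtraction clamps at zero and is monotone", {
  s <- rate_profile(c(0.010, 0.001, 0.004))
  b <- rate_profile(c(0.002, 0.005, 0.004))
  out <- subtract_background(s, b)
  expect_equal(out$sub_rate, c(0.008, 0, 0))
  expect_true(all(out$sub_rate >= 0))
  expect_true(all(out$sub_rate <= s$sub_rate))
  # identical profiles cancel exactly
  expect_true(all(subtract_background(s, s)$sub_rate == 0))
  # random property: clamped and bounded by the sample
  set.seed(5)
  for (k in 1:20) {
    s2 <- rate_profile(runif(50, 0, 0.01))
    b2 <- rate_profile(runif(50, 0, 0.01))
    out2 <- subtract_background(s2, b2)
    expect_true(all(out2$sub_rate >= 0 & out2$sub_rate <= s2$sub_rate + 1e-15))
  }
  expect_error(subtract_background(s, rate_profile(rep(0, 5))), "different")
})

test_that("window averages honour clipping and coverage exclusions", {
  prof <- rate_profile(rep(0.004, 101))
  expect_equal(window_average(prof, 51, 50), 0.004)
  half <- rate_profile(c(rep(0, 50), rep(0.008, 50)))
  expect_equal(window_average(half, 50, 50), 0.004)
  # clipped at the reference edge: mean over the clipped set only
  edge <- rate_profile(c(0.01, 0.02, 0.03, rep(0, 97)))
  expect_equal(window_average(edge, 1, 2), 0.02)
  # zero-coverage positions are excluded, not averaged as zeros
  pile <- pcol(c(100, 0, 100), pos = 1:3)
  pile$T <- c(10L, 0L, 0L)
  pile$depth_clean <- c(100L, 0L, 100L)
  prof2 <- mutation_profile(pile)
  expect_equal(window_average(prof2, 2, 1), 0.05)
  expect_error(window_average(prof, 1000, 5), "intersect")
})

test_that("generations accumulate as log2 of the OD fold changes", {
  expect_equal(generations_from_passages(
    tibble::tibble(od_start = 0.25, od_end = 0.5)), 1)
  expect_equal(generations_from_passages(
    tibble::tibble(od_start = 0.25, od_end = 0.25)), 0)
  # an 8-day, 4-passage schedule reaching OD 8.72 each time: ~20.5 doublings
  four <- tibble::tibble(od_start = rep(0.25, 4), od_end = rep(8.72, 4))
  expect_equal(generations_from_passages(four), 4 * log2(34.88))
  expect_equal(round(generations_from_passages(four), 1), 20.5)
  expect_error(generations_from_passages(
    tibble::tibble(od_start = 0, od_end = 1)), "positive")
  expect_error(generations_from_passages(
    tibble::tibble(od_start = 0.5, od_end = 0.25)), ">=")
})

test_that("per-generation normalization is plain division", {
  expect_equal(per_generation_rate(0, 20.5), 0)
  expect_equal(per_generation_rate(4.4e-3, 20.5), 4.4e-3 / 20.5)
  # inverse identity
  r <- 2.13e-4; g <- 20.5
  expect_equal(per_generation_rate(r * g, g), r)
  expect_error(per_generation_rate(0.1, 0), "> 0")
})

test_that("PAM-anchored combination shifts, flips and averages", {
  n <- 400
  set.seed(21)
  rates <- round(runif(n, 0, 0.01) * 1000) / 1000  # realizable at depth 1000
  prof <- rate_profile(rates)
  g_cod <- tibble::tibble(name = "a", spacer = strrep("A", 20),
                          strand = "coding", pam3_pos = 200L)
  comb <- combine_profiles(list(prof), g_cod, halfwidth = 100)
  # a single coding-strand guide is a pure shift of the input
  expect_equal(comb$mean_rate, rates[(200 - 100):(200 + 100)])
  expect_equal(comb$rel_pos, -100:100)
  # template-strand flip negates coordinates; applying it twice restores
  g_tem <- g_cod; g_tem$strand <- "template"
  flipped <- combine_profiles(list(prof), g_tem, halfwidth = 100)
  expect_equal(flipped$mean_rate, rev(comb$mean_rate))
  twice <- flipped
  twice$rel_pos <- -twice$rel_pos
  twice <- dplyr::arrange(twice, rel_pos)
  expect_equal(twice$mean_rate, comb$mean_rate)
  # two guides: mean (a+b)/2 at every shared relative position
  prof2 <- rate_profile(rev(rates))
  g2 <- dplyr::bind_rows(g_cod, dplyr::mutate(g_cod, name = "b", pam3_pos = 210L))
  comb2 <- combine_profiles(list(prof, prof2), g2, halfwidth = 50)
  a <- rates[(200 - 50):(200 + 50)]
  b <- rev(rates)[(210 - 50):(210 + 50)]
  expect_equal(comb2$mean_rate, (a + b) / 2)
  # permutation invariance
  comb2r <- combine_profiles(list(prof2, prof), g2[2:1, ], halfwidth = 50)
  expect_equal(comb2r$mean_rate, comb2$mean_rate)
  expect_equal(comb2$n_guides, rep(2L, 101))
})

test_that("depth weighting differs from the unweighted mean when depths differ", {
  p1 <- rate_profile(rep(0.01, 50))
  p2 <- rate_profile(rep(0.02, 50))
  p2$depth_clean <- 3000L
  g <- tibble::tibble(name = c("a", "b"), spacer = strrep("A", 20),
                      strand = "coding", pam3_pos = c(25L, 25L))
  eq <- combine_profiles(list(p1, p2), g, halfwidth = 10)
  wt <- combine_profiles(list(p1, p2), g, halfwidth = 10, weight = "depth")
  expect_equal(unique(eq$mean_rate), 0.015)
  expect_equal(unique(wt$mean_rate), (0.01 * 1000 + 0.02 * 3000) / 4000)
})

test_that("spectrum tallies match a hand tally and split by reference base", {
  # only C->T events: a single nonzero cell
  prof <- rate_profile(c(0.01, 0.02), refs = c("C", "C"))
  sp <- spectrum(prof, 1, 5)
  expect_equal(sp$matrix["C", "T"], 0.03)
  expect_equal(sum(sp$matrix), 0.03)
  expect_equal(sp$at_fraction, 0)
  # equal C->T and C->G mass in two cells
  pile <- dplyr::bind_rows(
    pcol(1000, c(A = 0, C = 0, G = 10, T = 0), refb = "C", pos = 1L),
    pcol(1000, c(A = 0, C = 0, G = 0, T = 10), refb = "C", pos = 2L))
  sp2 <- spectrum(mutation_profile(pile), 1, 5)
  expect_equal(sp2$matrix["C", "G"], sp2$matrix["C", "T"])
  # randomized profile equals a brute-force tally
  set.seed(8)
  n <- 30
  pile3 <- tibble::tibble(pos = 1:n,
                          ref = sample(c("A", "C", "G", "T"), n, TRUE),
                          depth_clean = 500L,
                          A = 0L, C = 0L, G = 0L, T = 0L, indel_count = 0L)
  for (i in 1:n) {
    for (b in setdiff(c("A", "C", "G", "T"), pile3$ref[i])) {
      pile3[[b]][i] <- sample(0:20, 1)
    }
  }
  prof3 <- mutation_profile(pile3)
  sp3 <- spectrum(prof3, 15, 14)
  manual <- matrix(0, 4, 4, dimnames = list(c("A", "C", "G", "T"),
                                            c("A", "C", "G", "T")))
  at_sig <- 0; tot_sig <- 0
  for (i in 1:29) {
    for (b in setdiff(c("A", "C", "G", "T"), pile3$ref[i])) {
      r <- pile3[[b]][i] / 500
      manual[pile3$ref[i], b] <- manual[pile3$ref[i], b] + r
      tot_sig <- tot_sig + r
      if (pile3$ref[i] %in% c("A", "T")) at_sig <- at_sig + r
    }
  }
  expect_equal(sp3$matrix, manual)
  expect_equal(sp3$at_fraction, at_sig / tot_sig)
  # total spectrum mass equals window mean times covered positions
  expect_equal(sum(sp3$matrix),
               window_average(prof3, 15, 14) * 29, tolerance = 1e-12)
})

test_that("indel rates follow indel/(clean+indel)", {
  expect_equal(indel_profile(pcol(100))$indel_rate, 0)
  expect_equal(indel_profile(pcol(19999, indel = 1))$indel_rate, 5e-5)
  expect_equal(indel_profile(pcol(0, indel = 50))$indel_rate, 1)
})

test_that("window extent matches the exhaustive-search oracle", {
  # all signal at one position
  one <- tibble::tibble(rel_pos = -10:10, mean_rate = c(rep(0, 10), 1, rep(0, 10)))
  expect_equal(estimate_window_extent(one, 0.99)$width_bp, 1L)
  # two equal point masses at +/-10 force the full bracket
  two <- tibble::tibble(rel_pos = -15:15, mean_rate = 0)
  two$mean_rate[two$rel_pos %in% c(-10, 10)] <- 0.5
  ext <- estimate_window_extent(two, 0.99)
  expect_equal(ext$width_bp, 21L)
  expect_equal(c(ext$left, ext$right), c(-10L, 10L))
  # uniform signal: agrees with the oracle (99% of 100 equal masses)
  uni <- tibble::tibble(rel_pos = -50:49, mean_rate = 0.004)
  expect_equal(estimate_window_extent(uni, 0.99)$width_bp,
               oracle_extent(uni$rel_pos, uni$mean_rate, 0.99))
  # randomized profiles agree with the oracle
  set.seed(11)
  for (k in 1:10) {
    x <- tibble::tibble(rel_pos = -30:30, mean_rate = runif(61)^3)
    expect_equal(estimate_window_extent(x, 0.95)$width_bp,
                 oracle_extent(x$rel_pos, x$mean_rate, 0.95))
  }
  expect_error(estimate_window_extent(
    tibble::tibble(rel_pos = 1:3, mean_rate = 0), 0.99), "signal")
})

test_that("per-read multiplicity summaries are exact and match Poisson theory", {
  s <- per_read_count_summary(c(0, 1, 2, 2))
  expect_equal(s$frac_ge1, 0.75)
  expect_equal(s$frac_ge2, 0.5)
  expect_equal(s$histogram$n, c(1L, 1L, 2L))
  expect_equal(per_read_count_summary(rep(0, 10))$frac_ge1, 0)
  set.seed(9)
  counts <- stats::rpois(20000, 0.7)
  p1 <- 1 - exp(-0.7)
  s2 <- per_read_count_summary(counts)
  expect_lt(abs(s2$frac_ge1 - p1), 3 * sqrt(p1 * (1 - p1) / 20000))
  expect_error(per_read_count_summary(integer(0)), "empty")
})

test_that("simulated parameters are recovered end to end", {
  # moderate-size recovery run: r inferred from the window mean / generations
  r <- 2.13e-4; g <- 20.5
  cfg <- simulation_config(ref, guide, base_rate = r, generations = g,
                           n_genomes = 4000, seed = 17)
  pool <- simulate_mutagenesis(cfg)
  reads <- sample_reads(pool, 2000, seed = 18)
  merged <- merge_read_pairs(reads)
  al <- suppressMessages(align_reads(merged, ref))
  prof <- mutation_profile(build_pileup(al, ref))
  est_p <- window_average(prof, guide$pam3_pos, 50)
  p_true <- 1 - (1 - r)^g
  se <- sqrt(p_true * (1 - p_true) * (1 / (4000 * 101) + 1 / (2000 * 101)))
  expect_lt(abs(est_p - p_true), 3 * se)
  r_hat <- per_generation_rate(est_p, g)
  expect_lt(abs(r_hat - r) / r, 0.15)
})
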