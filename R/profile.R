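# The core quantification: per-position substitution and indel rates,
# background subtraction, window averaging and per-generation normalization.
#
# The substitution rate at a position is the number of reads carrying a
# mismatch there divided by the number of reads covering the position
# cleanly (excluding reads with an insertion or deletion at the column).
# Zero-coverage positions carry rate 0 plus an explicit `covered = FALSE`
# flag and are excluded from window means rather than silently diluting
# them.

#' Per-position substitution rates
#'
#' @param pileup Pileup tibble (see [build_pileup()]).
#' @return Numeric vector of rates, 0 where `depth_clean` is 0.
#' @export
#' @examples
#' substitution_rate(tibble::tibble(pos = 1, ref = "C", depth_clean = 100,
#'                                  A = 0, C = 0, G = 0, T = 5, indel_count = 0))
substitution_rate <- function(pileup) {
  if (any(pileup$depth_clean < 0) || any(alt_total(pileup) < 0)) {
    abort("negative counts in pileup.")
  }
  if_else(pileup$depth_clean > 0, alt_total(pileup) / pileup$depth_clean, 0)
}

#' Build a mutation profile from a pileup
#'
#' Adds per-position substitution and indel rates (and the coverage flag) to
#' a pileup, yielding the table every downstream profiling operation
#' consumes.
#'
#' @param pileup Pileup tibble.
#' @return Profile tibble: pileup columns plus `sub_rate`, `indel_rate`,
#'   `covered`.
#' @export
mutation_profile <- function(pileup) {
  mutate(as_tibble(pileup),
         sub_rate = substitution_rate(pileup),
         indel_rate = if_else(.data$depth_clean + .data$indel_count > 0,
                              .data$indel_count /
                                (.data$depth_clean + .data$indel_count), 0),
         covered = .data$depth_clean > 0)
}

#' Subtract a background profile
#'
#' Per-position `rate' = max(0, rate_sample - rate_background)` for both
#' substitution and indel rates; negative differences are clamped to zero.
#' Counts and depths are carried from the sample. Sample and background may
#' have different depths but must describe the same reference.
#'
#' @param sample,background Profile tibbles over the same reference.
#' @return A profile tibble with subtracted rates.
#' @export
subtract_background <- function(sample, background) {
  if (nrow(sample) != nrow(background) ||
      any(sample$pos != background$pos) || any(sample$ref != background$ref)) {
    abort("sample and background profiles describe different references.")
  }
  mutate(sample,
         sub_rate = pmax(0, .data$sub_rate - background$sub_rate),
         indel_rate = pmax(0, .data$indel_rate - background$indel_rate))
}

#' Average substitution rate over a window
#'
#' Arithmetic mean of `sub_rate` over positions in
#' `[center - halfwidth, center + halfwidth]`, clipped to the reference
#' bounds; zero-coverage positions are excluded from the mean.
#'
#' @param profile Profile tibble.
#' @param center 1-based window center.
#' @param halfwidth Window half-width, bp.
#' @return A single mean rate.
#' @export
window_average <- function(profile, center, halfwidth) {
  sel <- profile$pos >= center - halfwidth & profile$pos <= center + halfwidth
  if (!any(sel)) abort("window does not intersect the reference.")
  sel <- sel & profile$covered
  if (!any(sel)) abort("no covered positions inside the window.")
  mean(profile$sub_rate[sel])
}

#' Per-position indel rates
#'
#' `indel_count / (depth_clean + indel_count)` per column.
#'
#' @param pileup Pileup tibble.
#' @return Tibble with `pos`, `ref`, `indel_rate`.
#' @export
indel_profile <- function(pileup) {
  tot <- pileup$depth_clean + pileup$indel_count
  tibble(pos = pileup$pos, ref = pileup$ref,
         indel_rate = if_else(tot > 0, pileup$indel_count / tot, 0))
}

#' Generations elapsed from culture passage records
#'
#' Number of doublings across serial passages:
#' sum over passages of log2(od_end / od_start).
#'
#' @param passages Tibble with columns `od_start`, `od_end` (OD600 units,
#'   both positive).
#' @return Total generations (real).
#' @export
#' @examples
#' generations_from_passages(tibble::tibble(od_start = 0.25, od_end = 0.5))
generations_from_passages <- function(passages) {
  passages <- as_tibble(passages)
  stopifnot(all(c("od_start", "od_end") %in% names(passages)))
  if (any(passages$od_start <= 0) || any(passages$od_end <= 0)) {
    abort("OD values must be positive.")
  }
  if (any(passages$od_end < passages$od_start)) {
    abort("od_end must be >= od_start within each passage.")
  }
  sum(log2(passages$od_end / passages$od_start))
}

#' Per-generation substitution rate
#'
#' Divides a cumulative window-mean substitution frequency by the number of
#' generations (linear division; at the magnitudes involved the compounding
#' correction `1 - (1 - p)^(1/g)` differs by under 0.2%).
#'
#' @param mean_rate Cumulative substitution frequency (substitutions/bp).
#' @param generations Elapsed generations, > 0.
#' @return Rate in substitutions per bp per generation (s.p.b.).
#' @export
per_generation_rate <- function(mean_rate, generations) {
  if (any(generations <= 0)) abort("`generations` must be > 0.")
  mean_rate / generations
}

#' Summarise per-read substitution multiplicities
#'
#' Histogram of per-read substitution counts plus the fractions of reads
#' carrying at least one and at least two substitutions.
#'
#' @param counts Integer vector of per-read substitution counts (see
#'   [substitutions_per_read()]).
#' @return List with `histogram` (tibble `count`, `n`), `frac_ge1`,
#'   `frac_ge2`.
#' @export
#' @examples
#' per_read_count_summary(c(0, 1, 2, 2))
per_read_count_summary <- function(counts) {
  if (length(counts) == 0L) abort("empty per-read count list.")
  tab <- count(tibble(count = as.integer(counts)), .data$count)
  list(histogram = tab,
       frac_ge1 = mean(counts >= 1),
       frac_ge2 = mean(counts >= 2))
}

#' Write and read profile TSV
#'
#' Profiles travel as TSV with columns `pos` (1-based), `ref`,
#' `depth_clean`, `A`, `C`, `G`, `T`, `indel_count`, `sub_rate`,
#' `indel_rate`, `covered`.
#'
#' @param profile Profile tibble.
#' @param path File path.
#' @return `read_profile_tsv()` returns a profile tibble;
#'   `write_profile_tsv()` returns `path` invisibly.
#' @export
write_profile_tsv <- function(profile, path) {
  readr::write_tsv(profile, path)
  invisible(path)
}

#' @rdname write_profile_tsv
#' @export
read_profile_tsv <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    pos = "i", ref = "c", depth_clean = "i", A = "i", C = "i", G = "i",
    T = "i", indel_count = "i", sub_rate = "d", indel_rate = "d",
    covered = "l"), progress = FALSE)
}
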