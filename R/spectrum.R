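# Substitution spectrum over a window: per-position ref->alt rates (the
# heatmap content), their 4x4 aggregate, and the share of total substitution
# signal occurring at A or T reference bases (the A/T fraction, a measure of
# how strictly the editor confines itself to C:G pairs).

#' Substitution spectrum of a profile window
#'
#' Per-position ref->alt substitution rates within
#' `[center - halfwidth, center + halfwidth]`, summed into an aggregate 4x4
#' matrix grouped by reference base, plus the A/T share of the total signal.
#'
#' @param profile Profile tibble (see [mutation_profile()]).
#' @param center 1-based window center.
#' @param halfwidth Window half-width, bp.
#' @return An object of class `spectrum_matrix`: list with `matrix` (4x4,
#'   rows = reference base, cols = alternative base, zero diagonal),
#'   `per_position` (tibble `pos`, `ref`, `alt`, `rate`), `at_fraction`,
#'   `window` (center, halfwidth).
#' @export
spectrum <- function(profile, center, halfwidth) {
  sel <- profile$pos >= center - halfwidth & profile$pos <= center + halfwidth
  if (!any(sel)) abort("window does not intersect the profile.")
  win <- profile[sel, ]
  long <- tidyr::pivot_longer(
    select(win, "pos", "ref", "depth_clean", dplyr::all_of(DNA_BASES)),
    cols = dplyr::all_of(DNA_BASES), names_to = "alt", values_to = "count")
  long <- mutate(long,
                 rate = if_else(.data$depth_clean > 0,
                                .data$count / .data$depth_clean, 0))
  long <- select(long, "pos", "ref", "alt", "rate")
  m <- matrix(0, 4, 4, dimnames = list(DNA_BASES, DNA_BASES))
  agg <- long %>%
    group_by(.data$ref, .data$alt) %>%
    summarise(rate = sum(.data$rate), .groups = "drop") %>%
    filter(.data$ref != .data$alt)
  m[cbind(agg$ref, agg$alt)] <- agg$rate
  total <- sum(m)
  at <- sum(m[c("A", "T"), ])
  structure(
    list(matrix = m,
         per_position = filter(long, .data$ref != .data$alt),
         at_fraction = if (total > 0) at / total else 0,
         window = c(center = center, halfwidth = halfwidth)),
    class = "spectrum_matrix"
  )
}

#' @export
print.spectrum_matrix <- function(x, ...) {
  cat(sprintf("<spectrum_matrix> window %d ± %d bp, A/T share %.3g%%\n",
              x$window["center"], x$window["halfwidth"], 100 * x$at_fraction))
  print(signif(x$matrix, 3))
  invisible(x)
}

#' Write a spectrum matrix as TSV
#'
#' @param spec A `spectrum_matrix`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_spectrum_tsv <- function(spec, path) {
  df <- as_tibble(spec$matrix, rownames = "ref")
  readr::write_tsv(df, path)
  invisible(path)
}
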