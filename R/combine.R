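# PAM-anchored combination of per-guide profiles. Relative coordinate 0 is
# the 3'-most base of the NGG on the protospacer strand; profiles of
# template-strand protospacers are flipped (coordinates negated) so that all
# guides share one orientation — applying the flip twice restores the
# original, making the transform an involution.

#' Combine per-guide profiles on PAM-relative coordinates
#'
#' Re-indexes each profile to the PAM-relative frame of its guide
#' (`pos - pam3_pos` for coding-strand protospacers, `pam3_pos - pos` for
#' template-strand ones), restricts to `±halfwidth`, and averages the
#' substitution rate across guides at every relative position with data.
#' The default is an unweighted mean; `weight = "depth"` weights each guide
#' by its clean depth at the position.
#'
#' @param profiles List of profile tibbles, one per guide.
#' @param guides Guide tibble with one row per profile (same order).
#' @param halfwidth Relative-coordinate range to keep, bp.
#' @param weight `"equal"` (default) or `"depth"`.
#' @return A `combined_profile` tibble: `rel_pos`, one `rate_<name>` column
#'   per guide, `n_guides`, `mean_rate`.
#' @export
combine_profiles <- function(profiles, guides, halfwidth = 100L,
                             weight = c("equal", "depth")) {
  weight <- match.arg(weight)
  guides <- as_tibble(guides)
  if (length(profiles) != nrow(guides)) {
    abort("`profiles` and `guides` must have one entry per guide.")
  }
  if (nrow(guides) == 0L) abort("at least one guide is required.")
  nm <- guides$name
  if (any(is.na(nm) | !nzchar(nm))) nm <- sprintf("guide%d", seq_len(nrow(guides)))
  long <- purrr::map2(profiles, seq_len(nrow(guides)), function(p, i) {
    rel <- pam_relative(p$pos, guides$strand[i], guides$pam3_pos[i])
    tibble(rel_pos = rel, guide = nm[i], rate = p$sub_rate,
           depth = p$depth_clean, covered = p$covered)
  })
  long <- bind_rows(long)
  long <- filter(long, abs(.data$rel_pos) <= halfwidth, .data$covered)
  if (nrow(long) == 0L) abort("no covered positions within ±halfwidth of any PAM.")
  means <- long %>%
    group_by(.data$rel_pos) %>%
    summarise(
      n_guides = dplyr::n(),
      mean_rate = if (weight == "equal") mean(.data$rate) else
        sum(.data$rate * .data$depth) / sum(.data$depth),
      .groups = "drop")
  wide <- tidyr::pivot_wider(select(long, "rel_pos", "guide", "rate"),
                             names_from = "guide", values_from = "rate",
                             names_prefix = "rate_")
  out <- arrange(left_join(wide, means, by = "rel_pos"), .data$rel_pos)
  class(out) <- c("combined_profile", class(out))
  out
}

#' Shortest interval holding a given fraction of the combined signal
#'
#' Finds the shortest contiguous relative-coordinate interval whose summed
#' mean rate reaches `coverage_frac` of the total; ties are broken by the
#' smaller |midpoint| (closest to the PAM), then by the leftmost interval.
#' Operationalizes the "mutagenic window extent" of a combined profile.
#'
#' @param combined A `combined_profile` (or tibble with `rel_pos`,
#'   `mean_rate`).
#' @param coverage_frac Fraction of total signal to capture.
#' @return One-row tibble with `left`, `right` (relative coordinates) and
#'   `width_bp = right - left + 1`.
#' @export
estimate_window_extent <- function(combined, coverage_frac = 0.99) {
  stopifnot(coverage_frac > 0, coverage_frac <= 1)
  x <- arrange(as_tibble(combined), .data$rel_pos)
  total <- sum(x$mean_rate)
  if (total <= 0) abort("combined profile has no positive signal.")
  target <- coverage_frac * total
  n <- nrow(x)
  cs <- cumsum(x$mean_rate)
  best <- NULL
  j <- 1L
  for (i in seq_len(n)) {
    if (j < i) j <- i
    # advance the right edge until the window [i, j] reaches the target
    while (j <= n && cs[j] - (if (i > 1L) cs[i - 1L] else 0) < target - 1e-12) {
      j <- j + 1L
    }
    if (j > n) break
    width <- x$rel_pos[j] - x$rel_pos[i] + 1L
    mid <- abs((x$rel_pos[i] + x$rel_pos[j]) / 2)
    cand <- c(width, mid, x$rel_pos[i])
    if (is.null(best) || cand[1] < best[1] ||
        (cand[1] == best[1] && (cand[2] < best[2] ||
                                (cand[2] == best[2] && cand[3] < best[3])))) {
      best <- cand
      best_ij <- c(i, j)
    }
  }
  if (is.null(best)) abort("no interval reaches the requested coverage fraction.")
  tibble(left = x$rel_pos[best_ij[1]], right = x$rel_pos[best_ij[2]],
         width_bp = as.integer(best[1]))
}

#' Write and read combined-profile TSV
#'
#' @param combined A `combined_profile`.
#' @param path File path.
#' @return `read_combined_tsv()` returns a `combined_profile`;
#'   `write_combined_tsv()` returns `path` invisibly.
#' @export
write_combined_tsv <- function(combined, path) {
  readr::write_tsv(as_tibble(combined), path)
  invisible(path)
}

#' @rdname write_combined_tsv
#' @export
read_combined_tsv <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  class(out) <- c("combined_profile", class(out))
  out
}
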