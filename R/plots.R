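# ggplot2 presentation of each result type. autoplot() methods return plain
# ggplot objects; plot_* wrappers are thin aliases.

#' Plot a mutation profile
#'
#' Per-position substitution rate along the amplicon.
#'
#' @param object Profile tibble from [mutation_profile()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
plot_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$pos, y = .data$sub_rate)) +
    ggplot2::geom_col(width = 1, fill = "grey30") +
    ggplot2::labs(x = "reference position (bp)",
                  y = "substitution rate (substitutions/bp)") +
    ggplot2::theme_minimal()
}

#' Plot a combined PAM-anchored profile
#'
#' Mean substitution rate against the distance from the PAM 3' end, with the
#' per-guide traces behind the mean.
#'
#' @param object A `combined_profile`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot combined_profile
#' @export
autoplot.combined_profile <- function(object, ...) {
  long <- tidyr::pivot_longer(
    as_tibble(object), dplyr::starts_with("rate_"),
    names_to = "guide", values_to = "rate", names_prefix = "rate_")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$rel_pos)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$rate, group = .data$guide),
                       colour = "grey70", na.rm = TRUE) +
    ggplot2::geom_line(data = as_tibble(object),
                       ggplot2::aes(y = .data$mean_rate), colour = "black") +
    ggplot2::labs(x = "distance from PAM 3' end (bp)",
                  y = "substitution rate (substitutions/bp)") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.combined_profile
#' @param combined A `combined_profile`.
#' @export
plot_combined <- function(combined, ...) autoplot.combined_profile(combined, ...)

#' Plot a substitution-spectrum heatmap
#'
#' Per-position ref->alt rates across the window, one row per substitution
#' type.
#'
#' @param object A `spectrum_matrix`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot spectrum_matrix
#' @export
autoplot.spectrum_matrix <- function(object, ...) {
  pp <- mutate(object$per_position,
               type = paste0(.data$ref, "→", .data$alt))
  ggplot2::ggplot(pp, ggplot2::aes(x = .data$pos, y = .data$type,
                                   fill = .data$rate)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "rate") +
    ggplot2::labs(x = "reference position (bp)", y = "substitution") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.spectrum_matrix
#' @param spec A `spectrum_matrix`.
#' @export
plot_spectrum <- function(spec, ...) autoplot.spectrum_matrix(spec, ...)

#' Plot a saturation-binding fit
#'
#' Titration points and the fitted isotherm on a log concentration axis.
#'
#' @param object A `binding_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot binding_fit
#' @export
autoplot.binding_fit <- function(object, ...) {
  aug <- augment.binding_fit(object)
  grid <- tibble(concentration = 10^seq(log10(min(aug$concentration)),
                                        log10(max(aug$concentration)),
                                        length.out = 200))
  scale <- if (isTRUE(object$normalized)) object$bmax else 1
  grid$signal <- (object$bmax * grid$concentration /
                    (object$kd + grid$concentration)) / scale
  ggplot2::ggplot(aug, ggplot2::aes(x = .data$concentration, y = .data$signal)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "antigen concentration (M)", y = "signal") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.binding_fit
#' @param fit A `binding_fit`.
#' @export
plot_binding <- function(fit, ...) autoplot.binding_fit(fit, ...)
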