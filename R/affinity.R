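# Saturation-binding analysis of antigen titrations. Model: the monovalent
# single-site isotherm
#
#   signal = bmax * c / (kd + c)
#
# fit by nonlinear least squares with a deterministic multi-start: kd is
# started on a log-spaced grid spanning the concentration range, bmax from
# the maximum signal, and the converged fit with the lowest residual sum of
# squares is kept (it must be no worse than every grid start).

#' Fit a saturation-binding isotherm
#'
#' @param data Tibble with columns `concentration` (molar, > 0) and `signal`
#'   (normalized fluorescence). At least 4 points with non-identical
#'   concentrations.
#' @param n_starts Number of log-spaced kd grid starts.
#' @param normalize When `TRUE`, signals are rescaled by the fitted `bmax`
#'   after fitting (so the reported curve saturates at 1); fitting itself is
#'   always on the raw signals to avoid biasing kd.
#' @return An object of class `binding_fit`: list with `kd`, `bmax`, `rss`,
#'   `se` (named, from the fit curvature), `fit` (the `nls` object), `data`.
#' @export
#' @examples
#' conc <- 10^seq(-11, -7, length.out = 8)
#' dat <- tibble::tibble(concentration = conc, signal = conc / (1e-9 + conc))
#' fit_saturation(dat)$kd
fit_saturation <- function(data, n_starts = 12L, normalize = FALSE) {
  data <- as_tibble(data)
  stopifnot(all(c("concentration", "signal") %in% names(data)))
  conc <- data$concentration
  sig <- data$signal
  if (length(conc) != length(sig)) abort("concentration and signal lengths differ.")
  if (length(conc) < 4L) abort("at least 4 titration points are required.")
  if (any(conc <= 0)) abort("concentrations must be positive.")
  if (length(unique(conc)) < 2L) abort("concentrations must not all be equal.")
  if (all(sig == 0)) abort("signals are all zero; nothing to fit.")
  kd_grid <- 10^seq(log10(min(conc)), log10(max(conc)), length.out = n_starts)
  bmax0 <- max(sig)
  best <- NULL
  start_rss <- numeric(0)
  df_fit <- tibble(concentration = conc, signal = sig)
  for (kd0 in kd_grid) {
    start_rss <- c(start_rss,
                   sum((sig - bmax0 * conc / (kd0 + conc))^2))
    fit <- tryCatch(
      minpack.lm::nlsLM(signal ~ bmax * concentration / (kd + concentration),
                        data = df_fit,
                        start = list(bmax = bmax0, kd = kd0),
                        lower = c(bmax = 1e-12, kd = 1e-18),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(resid(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) {
    abort(sprintf("fit did not converge from any start; best grid RSS %.4g at kd %.3g.",
                  min(start_rss), kd_grid[which.min(start_rss)]))
  }
  if (best$rss > min(start_rss) + 1e-12) {
    abort("converged fit is worse than a grid start; refusing the fit.")
  }
  est <- coef(best$fit)
  se <- tryCatch(sqrt(diag(vcov(best$fit))), error = function(e) {
    c(bmax = NA_real_, kd = NA_real_)
  })
  out_data <- df_fit
  if (normalize) out_data$signal <- out_data$signal / est[["bmax"]]
  structure(
    list(kd = est[["kd"]], bmax = est[["bmax"]], rss = best$rss,
         se = c(kd = unname(se["kd"]), bmax = unname(se["bmax"])),
         fit = best$fit, data = out_data, normalized = normalize),
    class = "binding_fit"
  )
}

#' @export
print.binding_fit <- function(x, ...) {
  cat(sprintf("<binding_fit> Kd = %.3g M (SE %.2g), Bmax = %.3g, RSS = %.3g\n",
              x$kd, x$se["kd"], x$bmax, x$rss))
  invisible(x)
}

#' Tidy a binding fit
#'
#' Broom-style one-row-per-term summary of a [fit_saturation()] result.
#'
#' @param x A `binding_fit`.
#' @param ... Unused.
#' @return Tibble with `term`, `estimate`, `std.error`.
#' @method tidy binding_fit
#' @export
tidy.binding_fit <- function(x, ...) {
  tibble(term = c("kd", "bmax"),
         estimate = c(x$kd, x$bmax),
         std.error = c(x$se[["kd"]], x$se[["bmax"]]))
}

#' Glance at a binding fit
#'
#' @param x A `binding_fit`.
#' @param ... Unused.
#' @return One-row tibble with `kd`, `bmax`, `rss`, `nobs`.
#' @method glance binding_fit
#' @export
glance.binding_fit <- function(x, ...) {
  tibble(kd = x$kd, bmax = x$bmax, rss = x$rss, nobs = nrow(x$data))
}

#' Augment titration data with fitted values
#'
#' @param x A `binding_fit`.
#' @param ... Unused.
#' @return The titration tibble plus `.fitted` and `.resid`.
#' @method augment binding_fit
#' @export
augment.binding_fit <- function(x, ...) {
  scale <- if (isTRUE(x$normalized)) x$bmax else 1
  mutate(x$data,
         .fitted = (x$bmax * .data$concentration /
                      (x$kd + .data$concentration)) / scale,
         .resid = .data$signal - .data$.fitted)
}

#' Fold improvement in affinity
#'
#' `kd_reference / kd_variant`: how many-fold tighter the variant binds than
#' the reference (lower Kd = tighter binding).
#'
#' @param kd_reference,kd_variant Dissociation constants, molar, > 0.
#' @return Dimensionless fold change.
#' @export
#' @examples
#' fold_improvement(3.58e-9, 1e-11)  # 358
fold_improvement <- function(kd_reference, kd_variant) {
  if (any(kd_reference <= 0) || any(kd_variant <= 0)) {
    abort("dissociation constants must be positive.")
  }
  kd_reference / kd_variant
}

#' Read a titration CSV
#'
#' Two columns: `concentration_molar`, `signal`.
#'
#' @param path File path.
#' @return Tibble with `concentration`, `signal`.
#' @export
read_titration <- function(path) {
  x <- readr::read_csv(path, col_types = "dd", progress = FALSE)
  names(x)[1:2] <- c("concentration", "signal")
  x
}

#' Write a binding-fit report as TSV
#'
#' @param fit A `binding_fit`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_fit_report <- function(fit, path) {
  readr::write_tsv(tidy.binding_fit(fit), path)
  invisible(path)
}
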