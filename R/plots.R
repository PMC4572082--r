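#' Plot psychometric curves
#'
#' Detection probability against amplitude, one panel per stimulus
#' combination, with Clopper-Pearson ribbons where available.
#'
#' @param object An `nd_curve` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot nd_curve
#' @export
autoplot.nd_curve <- function(object, ...) {
  df <- as_tibble(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$A, y = .data$psi,
                                        colour = .data$model))
  if (any(!is.na(df$ci_lo))) {
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$ci_lo, ymax = .data$ci_hi,
                   fill = .data$model),
      alpha = 0.2, colour = NA)
  }
  p + ggplot2::geom_line() +
    ggplot2::facet_wrap(~label) +
    ggplot2::labs(x = "amplitude A (mA)", y = "detection probability") +
    ggplot2::coord_cartesian(ylim = c(0, 1))
}

#' Plot a fitted hazard model over its reference curves
#'
#' Simulated drift-diffusion points (with exact binomial ribbons) overlaid
#' with the fitted hazard-model curve, one panel per combination.
#'
#' @param object An `hm_fit` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot hm_fit
#' @export
autoplot.hm_fit <- function(object, ...) {
  d <- as_tibble(object$curve_d)
  h <- as_tibble(object$curve_h)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$A)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_lo, ymax = .data$ci_hi),
                         alpha = 0.2) +
    ggplot2::geom_line(ggplot2::aes(y = .data$psi, colour = "DDM")) +
    ggplot2::geom_line(data = h,
                       ggplot2::aes(y = .data$psi, colour = "HM (fitted)"),
                       linetype = "dashed") +
    ggplot2::facet_wrap(~label) +
    ggplot2::labs(x = "amplitude A (mA)", y = "detection probability",
                  colour = NULL)
}

#' Plot the empirical fitting-error distribution of a Monte Carlo study
#'
#' @param object An `mc_study` object.
#' @param ... Unused.
#' @return A ggplot object (ECDF of the fitting errors).
#' @method autoplot mc_study
#' @export
autoplot.mc_study <- function(object, ...) {
  df <- tibble(error = object$errors)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$error)) +
    ggplot2::stat_ecdf() +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dotted") +
    ggplot2::labs(x = "fitting error E", y = expression(F[E]))
}

#' Plot an ensemble of drift-diffusion realizations
#'
#' Spaghetti plot of the stored path grid with the firing threshold.
#'
#' @param object A `ddm_paths` object from [ddm_simulate()].
#' @param max_paths Plot at most this many realizations.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ddm_paths
#' @export
autoplot.ddm_paths <- function(object, max_paths = 50, ...) {
  df <- tidy(object)
  keep <- unique(df$realization)
  keep <- keep[seq_len(min(length(keep), max_paths))]
  ggplot2::ggplot(df[df$realization %in% keep, ],
                  ggplot2::aes(x = .data$time, y = .data$x,
                               group = .data$realization)) +
    ggplot2::geom_line(alpha = 0.3) +
    ggplot2::geom_hline(yintercept = object$params$alpha2,
                        linetype = "dashed") +
    ggplot2::labs(x = "time (ms)", y = "lumped PSP x (A/s)")
}
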