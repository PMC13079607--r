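# ggplot2 views of the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an MMS spike train
#'
#' @param object An `mms_series`.
#' @param ... Unused.
#' @return A ggplot: per-frame spike amplitudes with zeros at the mean
#'   motion level.
#' @export
autoplot.mms_series <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$t, y = .data$value)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$t, yend = 0),
                          linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = "MMS amplitude") +
    ggplot2::ylim(0, 1)
}

#' Plot a fitted Gamma density
#'
#' @param object A `gamma_fit`.
#' @param data Optional spike sample to underlay as a histogram.
#' @param ... Unused.
#' @return A ggplot of the fitted shape--scale Gamma density.
#' @export
autoplot.gamma_fit <- function(object, data = NULL, ...) {
  xmax <- if (!is.null(data)) max(data) else
    stats::qgamma(0.999, object$shape, scale = object$scale)
  grid <- seq(1e-6, xmax, length.out = 400)
  dens <- tibble::tibble(x = grid,
                         y = dgamma(grid, object$shape, scale = object$scale))
  p <- ggplot2::ggplot()
  if (!is.null(data)) {
    p <- p + ggplot2::geom_histogram(
      data = tibble::tibble(x = data),
      ggplot2::aes(x = .data$x, y = ggplot2::after_stat(density)),
      bins = 40, fill = "grey80", colour = "grey50")
  }
  p + ggplot2::geom_line(data = dens,
                         ggplot2::aes(x = .data$x, y = .data$y),
                         colour = "firebrick") +
    ggplot2::labs(x = "MMS peak amplitude", y = "density",
                  subtitle = sprintf("shape %.3g, scale (NSR) %.3g",
                                     object$shape, object$scale))
}

#' Plot the cohort log-log shape--scale law
#'
#' @param object A `powerlaw_fit`.
#' @param ... Unused.
#' @return A ggplot of the log10 parameter-plane scatter with the fitted
#'   line.
#' @export
autoplot.powerlaw_fit <- function(object, ...) {
  d <- object$model$model
  names(d) <- c("log10_scale", "log10_shape")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$log10_shape,
                                  y = .data$log10_scale)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "firebrick") +
    ggplot2::labs(x = "log10 Gamma shape", y = "log10 Gamma scale (NSR)",
                  subtitle = sprintf("slope %.3f, R² %.3f",
                                     object$slope, object$r_squared))
}

#' Poincare plot of an IBI series
#'
#' @param ibi An `ibi_series` or numeric intervals (ms).
#' @return A ggplot of the lag-1 scatter annotated with SD1/SD2.
#' @export
plot_poincare <- function(ibi) {
  x <- clean_intervals(ibi)
  ps <- poincare_sd(x)
  d <- tibble::tibble(x = x[-length(x)], y = x[-1])
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.4) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "IBI(t) (ms)", y = "IBI(t+1) (ms)",
                  subtitle = sprintf("SD1 %.1f ms, SD2 %.1f ms",
                                     ps$sd1, ps$sd2))
}

#' Plot sorted vs matched transfer-entropy curves
#'
#' @param object A `te_curves` object.
#' @param ... Unused.
#' @return A ggplot: the sorted direction's monotone curve and the other
#'   direction's values in the same participant order.
#' @export
autoplot.te_curves <- function(object, ...) {
  d <- tidyr::pivot_longer(
    tibble::as_tibble(object)[c("rank", "sorted_te", "matched_te")],
    cols = c("sorted_te", "matched_te"),
    names_to = "curve", values_to = "te_bits")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$rank, y = .data$te_bits,
                                  colour = .data$curve)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "participant (sorted)", y = "TE (bits)",
                  colour = NULL,
                  subtitle = sprintf("sorted by %s",
                                     attr(object, "sort_direction")))
}
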