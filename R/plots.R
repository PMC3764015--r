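# Base-graphics display methods: double-plotted actograms, daily activity
# waveforms, and amplitude spectra.

#' Plot a double-plotted actogram
#'
#' @param x an `activity_raster` from [raster()].
#' @param main plot title.
#' @param ... passed to [graphics::image()].
#' @return invisibly, `x`.
#' @export
plot.activity_raster <- function(x, main = "Actogram", ...) {
  m <- unclass(x)
  fold <- attr(x, "fold_period_h")
  width_h <- if (attr(x, "double_plot")) 2 * fold else fold
  graphics::image(
    x = seq(0, width_h, length.out = ncol(m) + 1),
    y = seq_len(nrow(m) + 1) - 0.5,
    z = t(m[rev(seq_len(nrow(m))), , drop = FALSE]) * 1,
    col = c("white", "grey20"), xlab = "Time (h)", ylab = "Day",
    main = main, useRaster = TRUE, yaxt = "n", ...)
  at <- pretty(seq_len(nrow(m)))
  graphics::axis(2, at = nrow(m) - at + 1, labels = at)
  invisible(x)
}

#' Plot a windowed activity trace
#'
#' @param x an `activity_trace`.
#' @param days optional day range to display, e.g. `c(1, 3)`.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, `x`.
#' @export
plot.activity_trace <- function(x, days = NULL, ...) {
  d <- x
  if (!is.null(days)) {
    d <- d[d$time_s >= (days[1] - 1) * 86400 & d$time_s < days[2] * 86400, ]
  }
  graphics::plot(d$time_s / 3600, d$activity, type = "l",
                 xlab = "Time (h)", ylab = expression(Q[m] ~ (s^-1)), ...)
  invisible(x)
}

#' Plot an amplitude spectrum versus period
#'
#' @param x a `spectrum_df`.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, `x`.
#' @export
plot.spectrum_df <- function(x, ...) {
  graphics::plot(x$period_h, x$amplitude, type = "l", xlab = "Period (h)",
                 ylab = "Normalized amplitude", ...)
  invisible(x)
}
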