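# Analysis of simulated (or supplied) MA firing-rate series: sleep/wake
# scoring, activity proxies, actogram rasters, circadian-binned wake
# profiles, amplitude spectra, and period estimation.

# Accept either a niche_sim or (numeric series + sampling interval).
.series_input <- function(x, sampling_interval_s = NULL, field = "Q_m") {
  if (inherits(x, "niche_sim")) {
    list(y = x$trace[[field]], dt = x$record_stride_s,
         t0 = x$trace$time_s[1])
  } else {
    if (is.null(sampling_interval_s)) {
      stop("supply sampling_interval_s with a bare series", call. = FALSE)
    }
    list(y = as.numeric(x), dt = sampling_interval_s, t0 = 0)
  }
}

#' Score a firing-rate series into sleep/wake bouts
#'
#' Pointwise thresholding of the MA firing rate (awake iff strictly above
#' threshold; ties score as sleep for determinism) followed by merging of
#' consecutive samples into alternating bouts. No smoothing is applied.
#'
#' @param x a `niche_sim` or numeric Q_m series.
#' @param threshold wake threshold (1/s); defaults to the simulation's.
#' @param sampling_interval_s sampling interval for a bare series.
#' @return a `bout_series`: data.frame with `start_s`, `end_s`, `state`
#'   (`"wake"`/`"sleep"`); attributes `span_s`, `t0_s`.
#' @export
score_sleep_wake <- function(x, threshold = NULL,
                             sampling_interval_s = NULL) {
  if (is.null(threshold)) {
    threshold <- if (inherits(x, "niche_sim")) x$wake_threshold else 1
  }
  stopifnot(threshold > 0)
  inp <- .series_input(x, sampling_interval_s)
  if (length(inp$y) == 0) stop("empty series", call. = FALSE)
  awake <- inp$y > threshold
  r <- rle(awake)
  ends <- cumsum(r$lengths)
  starts <- c(1L, head(ends, -1L) + 1L)
  out <- data.frame(
    start_s = inp$t0 + (starts - 1L) * inp$dt,
    end_s = inp$t0 + ends * inp$dt,
    state = ifelse(r$values, "wake", "sleep"),
    stringsAsFactors = FALSE
  )
  structure(out, class = c("bout_series", "data.frame"),
            span_s = length(inp$y) * inp$dt, t0_s = inp$t0)
}

#' Total sleep percentage
#'
#' @param bouts a `bout_series`.
#' @return percent of the record spent asleep (wake% + sleep% = 100).
#' @export
total_sleep_fraction <- function(bouts) {
  stopifnot(inherits(bouts, "bout_series"), nrow(bouts) > 0)
  dur <- bouts$end_s - bouts$start_s
  100 * sum(dur[bouts$state == "sleep"]) / sum(dur)
}

#' Windowed activity proxy
#'
#' Time-averages the MA firing rate in windows of fixed width (default 10
#' min), the model's proxy for activity counts. `"non-overlapping"` windows
#' step by one width; `"sliding"` windows step by one sample.
#'
#' @param x a `niche_sim` or numeric Q_m series.
#' @param width_s window width (s).
#' @param mode `"non-overlapping"` or `"sliding"`.
#' @param sampling_interval_s sampling interval for a bare series.
#' @return an `activity_trace`: data.frame with `time_s` (window centers) and
#'   `activity` (mean Q_m, 1/s); attribute `width_s`, `mode`.
#' @export
activity_trace <- function(x, width_s = 600,
                           mode = c("non-overlapping", "sliding"),
                           sampling_interval_s = NULL) {
  mode <- match.arg(mode)
  inp <- .series_input(x, sampling_interval_s)
  w <- round(width_s / inp$dt)
  if (w < 1) stop("window shorter than the sampling interval", call. = FALSE)
  y <- inp$y
  if (mode == "non-overlapping") {
    nw <- length(y) %/% w
    if (nw < 1) stop("record shorter than one window", call. = FALSE)
    m <- colMeans(matrix(y[seq_len(nw * w)], nrow = w))
    centers <- inp$t0 + (seq_len(nw) - 0.5) * w * inp$dt
  } else {
    if (length(y) < w) stop("record shorter than one window", call. = FALSE)
    cs <- cumsum(c(0, y))
    m <- (cs[(w + 1):length(cs)] - cs[1:(length(cs) - w)]) / w
    centers <- inp$t0 + (seq_along(m) - 1 + w / 2) * inp$dt
  }
  structure(data.frame(time_s = centers, activity = m),
            class = c("activity_trace", "data.frame"),
            width_s = w * inp$dt, mode = mode)
}

#' Actogram raster matrix
#'
#' Folds a windowed activity trace at `fold_period_h`, marking cells where
#' activity exceeds `high_threshold`. Rows are consecutive periods; with
#' `double_plot = TRUE` each row is concatenated with the next (the
#' conventional double-plotted actogram).
#'
#' @param trace an `activity_trace` (or `niche_sim`, converted with 10-min
#'   sliding windows as used for the degu rasters).
#' @param fold_period_h fold period (h), default 24.
#' @param double_plot concatenate consecutive rows?
#' @param high_threshold activity level (1/s) scored as a high-activity bar.
#' @return logical matrix (class `activity_raster`), one row per period;
#'   attributes `fold_period_h`, `bin_s`, `double_plot`.
#' @export
raster <- function(trace, fold_period_h = 24, double_plot = TRUE,
                   high_threshold = 1) {
  stopifnot(fold_period_h > 0)
  if (inherits(trace, "niche_sim")) {
    trace <- activity_trace(trace, mode = "sliding")
  }
  stopifnot(inherits(trace, "activity_trace"))
  dt <- diff(trace$time_s[1:2])
  per_s <- fold_period_h * 3600
  nbin <- round(per_s / dt)
  ndays <- floor(nrow(trace) / nbin)
  if (ndays < 1) stop("record shorter than one fold period", call. = FALSE)
  hi <- trace$activity[seq_len(ndays * nbin)] > high_threshold
  m <- matrix(hi, nrow = ndays, ncol = nbin, byrow = TRUE)
  if (double_plot) {
    m2 <- rbind(m[-1, , drop = FALSE], matrix(FALSE, 1, nbin))
    m <- cbind(m, m2)
  }
  structure(m, class = "activity_raster", fold_period_h = fold_period_h,
            bin_s = dt, double_plot = double_plot)
}

#' Percentage wake by circadian bin
#'
#' Folds the scored record at a fixed period and averages the wake fraction
#' in each phase bin over all cycles. Phase zero is set to the first bin with
#' more than 50% average wake that follows a bin at or below 50% (the rule
#' used to align intact and lesioned records on circadian time).
#'
#' @param bouts a `bout_series`.
#' @param period_h fold period (h), e.g. the intact animal's 25.0-h period.
#' @param n_bins number of phase bins (default 24: one bin per "circadian
#'   hour").
#' @param align apply the phase-zero rule? If `FALSE` bins start at the
#'   record's time origin.
#' @return data.frame with `bin` (0-based), `circadian_h` (bin center on a
#'   24-h circadian-time scale), `pct_wake`.
#' @export
percent_wake_by_circadian_bin <- function(bouts, period_h, n_bins = 24,
                                          align = TRUE) {
  stopifnot(inherits(bouts, "bout_series"), period_h > 0)
  span <- attr(bouts, "span_s")
  if (span < period_h * 3600) {
    stop("record shorter than one fold period", call. = FALSE)
  }
  step <- 60
  t <- seq(attr(bouts, "t0_s"), by = step, length.out = floor(span / step))
  awake <- rep(FALSE, length(t))
  wk <- bouts[bouts$state == "wake", , drop = FALSE]
  for (i in seq_len(nrow(wk))) {
    awake[t >= wk$start_s[i] & t < wk$end_s[i]] <- TRUE
  }
  phase <- ((t - t[1]) %% (period_h * 3600)) / (period_h * 3600)
  bin <- pmin(floor(phase * n_bins), n_bins - 1)
  pct <- 100 * tapply(awake, factor(bin, levels = 0:(n_bins - 1)), mean)
  pct <- as.numeric(pct)
  pct[is.na(pct)] <- 0
  if (align) {
    above <- pct > 50
    prev <- c(above[n_bins], head(above, -1L))
    z <- which(above & !prev)
    if (length(z)) pct <- pct[((seq_len(n_bins) - 1 + z[1] - 1) %% n_bins) + 1]
  }
  data.frame(bin = 0:(n_bins - 1),
             circadian_h = (0:(n_bins - 1) + 0.5) * 24 / n_bins,
             pct_wake = pct)
}

# Largest 5-smooth (2^a 3^b 5^c) integer <= n, so fft() never sees a length
# with a large prime factor.
.smooth_length <- function(n) {
  best <- 1
  p2 <- 1
  while (p2 <= n) {
    p23 <- p2
    while (p23 <= n) {
      p235 <- p23
      while (p235 <= n) {
        if (p235 > best) best <- p235
        p235 <- p235 * 5
      }
      p23 <- p23 * 3
    }
    p2 <- p2 * 2
  }
  best
}

#' Amplitude spectrum versus period
#'
#' Discrete-Fourier amplitude spectrum of the mean-removed, Hann-windowed
#' series, mapped from frequency to period, restricted to a period band, and
#' normalized so the trapezoidal integral of amplitude over the band equals
#' 1.
#'
#' @param x a `niche_sim` or numeric series.
#' @param band period band in hours, `c(min, max)`.
#' @param sampling_interval_s sampling interval for a bare series.
#' @return a `spectrum_df`: data.frame with `period_h` (increasing) and
#'   `amplitude` (area-normalized).
#' @export
amplitude_spectrum <- function(x, band = c(2, 30),
                               sampling_interval_s = NULL) {
  inp <- .series_input(x, sampling_interval_s)
  y <- inp$y
  ny <- .smooth_length(length(y))  # keep the FFT O(n log n)
  y <- y[seq_len(ny)]
  if (ny * inp$dt < 2 * band[2] * 3600) {
    stop("record must cover at least twice the longest band period",
         call. = FALSE)
  }
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, ny - 1) / (ny - 1))  # Hann
  yw <- (y - mean(y)) * w
  amp <- Mod(fft(yw))[2:floor(ny / 2)] * 2 / sum(w)
  freq <- (1:(floor(ny / 2) - 1)) / (ny * inp$dt)  # Hz
  period_h <- 1 / freq / 3600
  keep <- period_h >= band[1] & period_h <= band[2]
  if (!any(keep)) stop("band outside resolvable range", call. = FALSE)
  ph <- period_h[keep]
  am <- amp[keep]
  o <- order(ph)
  ph <- ph[o]
  am <- am[o]
  area <- sum(diff(ph) * (head(am, -1) + tail(am, -1)) / 2)
  if (area > 0) am <- am / area
  structure(data.frame(period_h = ph, amplitude = am),
            class = c("spectrum_df", "data.frame"), band_h = band)
}

#' Period of maximum spectral amplitude in a band
#'
#' @param spec a `spectrum_df` from [amplitude_spectrum()].
#' @param band optional sub-band (h) to search.
#' @return period (h) of the amplitude maximum.
#' @export
peak_period <- function(spec, band = NULL) {
  stopifnot(inherits(spec, "spectrum_df"))
  d <- spec
  if (!is.null(band)) d <- d[d$period_h >= band[1] & d$period_h <= band[2], ]
  if (nrow(d) == 0) stop("empty band", call. = FALSE)
  d$period_h[which.max(d$amplitude)]
}

# Main daily sleep onsets: greedy cycle-by-cycle selection of the onset of
# the longest sleep bout within a window around the expected next onset.
.main_sleep_onsets <- function(bouts, period_guess_h = 24) {
  sl <- bouts[bouts$state == "sleep", , drop = FALSE]
  sl$dur <- sl$end_s - sl$start_s
  P <- period_guess_h * 3600
  t_end <- max(bouts$end_s)
  w <- sl[sl$start_s < bouts$start_s[1] + P, , drop = FALSE]
  if (nrow(w) == 0) return(numeric(0))
  onsets <- w$start_s[which.max(w$dur)]
  repeat {
    lo <- onsets[length(onsets)] + 0.5 * P
    hi <- onsets[length(onsets)] + 1.5 * P
    if (lo > t_end) break
    w <- sl[sl$start_s >= lo & sl$start_s < hi, , drop = FALSE]
    if (nrow(w) == 0) break
    onsets <- c(onsets, w$start_s[which.max(w$dur)])
  }
  onsets
}

#' Free-running period from main sleep onset drift
#'
#' Identifies the main sleep onset of each cycle (the longest sleep bout in a
#' sliding window of about one fold period) and returns the least-squares
#' slope of onset time versus cycle number, in hours: i.e. 24 h plus the
#' daily clock-time drift of the onset. A non-monophasic record with too few
#' main onsets errors, or — when the underlying series is supplied — falls
#' back to the spectral fundamental with a warning.
#'
#' @param bouts a `bout_series`.
#' @param period_guess_h initial guess for the cycle length (h).
#' @param min_onsets minimum number of main onsets required.
#' @param series optional numeric activity series (with
#'   `sampling_interval_s`) used for the spectral fallback.
#' @param sampling_interval_s sampling interval of `series` (s).
#' @return estimated free-running period (h).
#' @export
free_running_period <- function(bouts, period_guess_h = 24,
                                min_onsets = 10, series = NULL,
                                sampling_interval_s = NULL) {
  stopifnot(inherits(bouts, "bout_series"))
  onsets <- .main_sleep_onsets(bouts, period_guess_h)
  if (length(onsets) >= 3) {
    # refine the window with a first-pass period estimate
    P1 <- mean(diff(onsets)) / 3600
    onsets <- .main_sleep_onsets(bouts, P1)
  }
  if (length(onsets) < min_onsets) {
    if (!is.null(series)) {
      warning("too few main sleep onsets; falling back to the spectral ",
              "fundamental")
      sp <- amplitude_spectrum(series, band = c(18, 32),
                               sampling_interval_s = sampling_interval_s)
      return(peak_period(sp))
    }
    if (length(onsets) < 3) stop("too few main sleep onsets", call. = FALSE)
    warning("few main sleep onsets; estimate may be unreliable")
  }
  k <- seq_along(onsets)
  unname(coef(lm(onsets ~ k))[2] / 3600)
}
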