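# Packaged experiments: one driver per study condition, assembling preset +
# protocol, simulating, and reducing to comparable metrics.

.light_mask_for_schedule <- function(schedule, times_s) {
  schedule_lux(schedule, times_s) > 0
}

# Diurnality index: (wake% during the light phase - wake% during the dark
# phase) / 100, in [-1, 1]; +1 fully diurnal, -1 fully nocturnal. The light
# phase is taken from a template schedule so the index is defined in DD by
# the projected (subjective) day.
.diurnality_index <- function(sim, template_schedule) {
  lt <- .light_mask_for_schedule(template_schedule, sim$trace$time_s)
  aw <- sim$trace$awake
  mean(aw[lt]) - mean(aw[!lt])
}

#' Count modality of a daily activity waveform
#'
#' Folds an activity trace at 24 h, smooths with a centered 30-min moving
#' average, and counts strict local maxima on the circular waveform; peaks
#' closer than `merge_h` are merged and peaks of prominence below
#' `min_prominence` times the waveform range are ignored.
#'
#' @param trace an `activity_trace` (10-min non-overlapping windows work
#'   well).
#' @param fold_period_h fold period (h).
#' @param smooth_s smoothing window (s).
#' @param merge_h peaks closer than this (h) count once.
#' @param min_prominence minimum peak height above the higher flanking
#'   minimum, as a fraction of the waveform range.
#' @return list with `n_peaks`, `peak_times_h`, `waveform` (data.frame
#'   `time_h`, `activity`).
#' @export
waveform_modality <- function(trace, fold_period_h = 24, smooth_s = 1800,
                              merge_h = 2, min_prominence = 0.1) {
  stopifnot(inherits(trace, "activity_trace"))
  dt <- diff(trace$time_s[1:2])
  nbin <- round(fold_period_h * 3600 / dt)
  phase <- floor(((trace$time_s - trace$time_s[1]) %% (nbin * dt)) / dt)
  wave <- as.numeric(tapply(trace$activity,
                            factor(phase, levels = 0:(nbin - 1)), mean))
  k <- max(1L, round(smooth_s / dt))
  if (k %% 2 == 0) k <- k + 1L
  padded <- c(tail(wave, k), wave, head(wave, k))
  sm <- stats::filter(padded, rep(1 / k, k), sides = 2)
  wave_s <- as.numeric(sm[(k + 1):(k + nbin)])
  # plateau-safe circular peak finding: collapse runs of equal values, mark
  # runs higher than both neighbors
  r <- rle(wave_s)
  nr <- length(r$values)
  pk <- integer(0)
  if (nr > 1) {
    run_end <- cumsum(r$lengths)
    run_mid <- run_end - (r$lengths - 1) / 2
    nxt <- c(r$values[-1], r$values[1])
    prv <- c(r$values[nr], r$values[-nr])
    pk <- round(run_mid[r$values > prv & r$values > nxt])
  }
  rng <- diff(range(wave_s))
  if (length(pk) > 1 && rng > 0) {
    # merge circularly-close peaks (keep the higher), then drop peaks of low
    # prominence: height above the deepest saddle on the walk to a higher
    # peak, in either direction
    repeat {
      tm <- (pk - 1) * dt / 3600
      if (length(pk) < 2) break
      gap <- diff(c(tm, tm[1] + fold_period_h))
      j <- which(gap < merge_h)
      if (!length(j)) break
      a <- j[1]
      b <- if (a == length(pk)) 1L else a + 1L
      pk <- pk[-(if (wave_s[pk[a]] < wave_s[pk[b]]) a else b)]
    }
    prominence <- function(i) {
      h <- wave_s[pk[i]]
      sad <- -Inf
      for (dir in c(-1L, 1L)) {
        j <- pk[i]
        lo <- h
        steps <- 0
        while (steps < nbin) {
          j <- ((j - 1 + dir) %% nbin) + 1
          if (wave_s[j] > h) break
          lo <- min(lo, wave_s[j])
          steps <- steps + 1
        }
        if (steps < nbin) sad <- max(sad, lo)  # found a higher point
      }
      if (is.infinite(sad)) rng else h - sad  # global max: full range
    }
    keep <- vapply(seq_along(pk), function(i) {
      prominence(i) >= min_prominence * rng
    }, TRUE)
    pk <- pk[keep]
  }
  list(n_peaks = length(pk), peak_times_h = (pk - 1) * dt / 3600,
       waveform = data.frame(time_h = (0:(nbin - 1)) * dt / 3600,
                             activity = wave_s))
}

.new_report <- function(id, metrics, provenance, ...) {
  structure(list(id = id, metrics = metrics, provenance = provenance, ...),
            class = "experiment_report")
}

#' @export
print.experiment_report <- function(x, ...) {
  cat(sprintf("<experiment_report> %s\n", x$id))
  m <- unlist(x$metrics)
  for (nm in names(m)) cat(sprintf("  %-32s %.4g\n", nm, m[nm]))
  invisible(x)
}

#' Sweep the SPZ modulation factor (nocturnal-diurnal spectrum)
#'
#' Simulates a rodent entrained to LD 12:12 (100 lux) for each value of
#' `nu_spz`, with masking and the DMH/LHA relay omitted so SPZ modulation is
#' examined in isolation. Reports, per value, the diurnality index
#' (wake% in light - wake% in dark)/100, total wake%, and the averaged 10-min
#' activity profile.
#'
#' @param values `nu_spz` values in \[-1, 1\].
#' @param preset preset name, default `"rodent_generic"`.
#' @param days simulated days after burn-in.
#' @param seed integer seed.
#' @param cfg optional [integrator_config()] (seed is overridden).
#' @return `experiment_report` with `metrics$diurnality_index`,
#'   `metrics$total_wake_pct`, and `profiles` (list of activity traces).
#' @export
run_nu_sweep <- function(values = c(-1, -0.5, 0, 0.5, 1),
                         preset = "rodent_generic", days = 30, seed = 1L,
                         cfg = NULL) {
  stopifnot(all(values >= -1 & values <= 1))
  pre <- load_preset(preset)
  sched <- ld_cycle(8, 20, lux = 100)
  if (is.null(cfg)) cfg <- integrator_config()
  di <- wk <- numeric(length(values))
  profiles <- vector("list", length(values))
  for (i in seq_along(values)) {
    p <- apply_overrides(pre$params, list(nu_spz = values[i], m_mask = 0,
                                          g_dmh_lha = 0))
    cfg$seed <- as.integer(seed + i - 1L)
    sim <- simulate_model(p, days, cfg, schedule = sched)
    di[i] <- .diurnality_index(sim, sched)
    wk[i] <- 100 * mean(sim$trace$awake)
    profiles[[i]] <- activity_trace(sim)
  }
  .new_report(
    "nu_sweep",
    metrics = list(nu_spz = values, diurnality_index = di,
                   total_wake_pct = wk),
    provenance = list(preset = preset, days = days, seed = seed,
                      dt = cfg$dt, schedule = "LD 12:12, 100 lux"),
    profiles = profiles
  )
}

#' Cooperative versus competitive DMH relays
#'
#' Simulates a primate under LD (500 lux, clock 6-18) with the DMH/LHA relay
#' excitatory (cooperative, `g_dmh_lha > 0`) or inhibitory (competitive,
#' `g_dmh_lha < 0`), masking omitted. Reports the modality (number of peaks)
#' of the averaged daily activity waveform and the averaged circadian
#' wake-drive and homeostatic waveforms underlying it.
#'
#' @param preset preset name, default `"primate_generic"`.
#' @param g_lha_strength magnitude of the DMH/LHA gain; cooperative uses
#'   `+g`, competitive `-g`. Default: the preset's `|g_dmh_lha|`.
#' @param days simulated days after burn-in.
#' @param seed integer seed.
#' @param cfg optional [integrator_config()].
#' @return `experiment_report` with per-mode modality and waveforms.
#' @export
run_relay_modes <- function(preset = "primate_generic",
                            g_lha_strength = NULL, days = 60, seed = 1L,
                            cfg = NULL) {
  pre <- load_preset(preset)
  if (is.null(g_lha_strength)) g_lha_strength <- abs(pre$params$relay$g_dmh_lha)
  stopifnot(g_lha_strength > 0)
  sched <- ld_cycle(6, 18, lux = 500)
  if (is.null(cfg)) cfg <- integrator_config()
  modes <- c(cooperative = g_lha_strength, competitive = -g_lha_strength)
  out <- list()
  n_peaks <- numeric(0)
  for (nm in names(modes)) {
    p <- apply_overrides(pre$params, list(g_dmh_lha = modes[[nm]],
                                          m_mask = 0))
    cfg$seed <- as.integer(seed)
    sim <- simulate_model(p, days, cfg, schedule = sched)
    tr <- activity_trace(sim)
    md <- waveform_modality(tr)
    # averaged daily waveforms of the two circadian wake drives and H
    rel <- p$relay
    s_rel <- rel$c_offset + rel$nu_spz * rel$scn_gain *
      pacemaker_output(sim$trace$x, sim$trace$x_c, rel$relay_phase_h,
                       p$pacemaker$tau_c_h)
    drives <- data.frame(
      time_s = sim$trace$time_s,
      dmh_vlpo_wake_drive = rel$g_dmh_vlpo * s_rel,
      dmh_lha_wake_drive = rel$g_dmh_lha * s_rel,
      H = sim$trace$H
    )
    fold <- function(v) {
      ph <- floor(((drives$time_s - drives$time_s[1]) %% 86400) / 600)
      as.numeric(tapply(v, factor(ph, levels = 0:143), mean))
    }
    out[[nm]] <- list(
      n_peaks = md$n_peaks, peak_times_h = md$peak_times_h,
      waveform = md$waveform,
      drive_waveforms = data.frame(
        time_h = (0:143) / 6,
        dmh_vlpo_wake_drive = fold(drives$dmh_vlpo_wake_drive),
        dmh_lha_wake_drive = fold(drives$dmh_lha_wake_drive),
        H = fold(drives$H)
      )
    )
    n_peaks[nm] <- md$n_peaks
  }
  .new_report(
    "relay_modes",
    metrics = list(n_peaks_cooperative = n_peaks[["cooperative"]],
                   n_peaks_competitive = n_peaks[["competitive"]]),
    provenance = list(preset = preset, days = days, seed = seed,
                      g_lha_strength = g_lha_strength,
                      schedule = "LD 500 lux, 6-18 h"),
    modes = out
  )
}

#' Degu temporal-niche switching
#'
#' Runs the 108-day running-wheel protocol (see [build_degu_protocol()])
#' under one of three inversion hypotheses and reports the per-epoch
#' diurnality index plus the double-plotted activity raster. In DD the index
#' is computed against the projected light phase of the LD schedule.
#'
#' @param hypothesis `"both"`, `"circadian_only"`, or `"masking_only"`.
#' @param days protocol length (108 reproduces the full experiment).
#' @param seed integer seed.
#' @param cfg optional [integrator_config()].
#' @param high_threshold raster high-activity threshold (1/s).
#' @return `experiment_report` with per-epoch diurnality indices, the bout
#'   series, and the raster matrix.
#' @export
run_degu_switch <- function(hypothesis = c("both", "circadian_only",
                                           "masking_only"),
                            days = 108, seed = 1L, cfg = NULL,
                            high_threshold = 1) {
  hypothesis <- match.arg(hypothesis)
  proto <- build_degu_protocol(hypothesis)
  if (is.null(cfg)) cfg <- integrator_config()
  cfg$seed <- as.integer(seed)
  sim <- simulate_model(proto, days, cfg)
  template <- ld_cycle(8, 20, lux = 30)
  # wheel_DD_onset covers the first three DD days: with a 23-h clock the
  # free-running rhythm drifts ~1 h/day, so longer averages decorrelate
  # clock time from circadian phase
  epochs <- list(wheel_LD1 = c(1, 22), no_wheel_LD = c(23, 67),
                 wheel_LD2 = c(68, min(88, days)),
                 wheel_DD = c(89, min(108, days)),
                 wheel_DD_onset = c(89, min(91, days)))
  di <- sapply(epochs, function(rng) {
    if (rng[2] < rng[1]) return(NA_real_)
    sel <- sim$trace$time_s >= (rng[1] - 1) * 86400 &
      sim$trace$time_s < rng[2] * 86400
    sub <- sim
    sub$trace <- sim$trace[sel, , drop = FALSE]
    .diurnality_index(sub, template)
  })
  tr <- activity_trace(sim, mode = "sliding")
  ras <- raster(tr, high_threshold = high_threshold)
  .new_report(
    paste0("degu_switch_", hypothesis),
    metrics = as.list(setNames(di, paste0("diurnality_", names(di)))),
    provenance = list(hypothesis = hypothesis, days = days, seed = seed,
                      dt = cfg$dt, preset = "degu"),
    sim = sim, raster = ras
  )
}

#' Squirrel-monkey SCN lesion experiment
#'
#' Simulates the constant-light (500 lux) protocol with intact or lesioned
#' SCN and reports total sleep percentage, the 2-30 h amplitude spectrum of
#' Q_m, the dominant ultradian (2-12 h band, lesioned) or circadian
#' fundamental (20-30 h band, intact) period, the circadian-binned wake
#' profile, and (intact) the free-running period from sleep-onset drift.
#'
#' @param lesioned logical.
#' @param chi_scale multiplier on the homeostatic time constant.
#' @param days simulated days after burn-in.
#' @param seed integer seed.
#' @param cfg optional [integrator_config()].
#' @param bin_period_h fold period for the circadian-binned profile (h).
#' @return `experiment_report`.
#' @export
run_scn_lesion <- function(lesioned = FALSE, chi_scale = 1, days = 60,
                           seed = 1L, cfg = NULL, bin_period_h = 25) {
  stopifnot(chi_scale > 0)
  pre <- load_preset("squirrel_monkey")
  p <- apply_overrides(pre$params,
                       list(chi_h = pre$params$homeostat$chi_h * chi_scale))
  proto <- build_lesion_protocol(lesioned, params = p)
  if (is.null(cfg)) cfg <- integrator_config()
  cfg$seed <- as.integer(seed)
  sim <- simulate_model(proto, days, cfg)
  bouts <- score_sleep_wake(sim)
  spec <- amplitude_spectrum(sim, band = c(2, 30))
  metrics <- list(total_sleep_pct = total_sleep_fraction(bouts))
  if (lesioned) {
    metrics$ultradian_peak_h <- peak_period(spec, band = c(2, 12))
  } else {
    metrics$fundamental_period_h <- peak_period(spec, band = c(20, 30))
    metrics$free_running_period_h <-
      tryCatch(free_running_period(bouts, period_guess_h = bin_period_h),
               error = function(e) NA_real_)
  }
  profile <- percent_wake_by_circadian_bin(bouts, period_h = bin_period_h)
  .new_report(
    paste0("scn_lesion_", if (lesioned) "lesioned" else "intact"),
    metrics = metrics,
    provenance = list(lesioned = lesioned, chi_scale = chi_scale,
                      days = days, seed = seed, dt = cfg$dt,
                      preset = "squirrel_monkey",
                      params = as.list(internal_param_vector(proto$params))),
    sim = sim, bouts = bouts, spectrum = spec, wake_profile = profile
  )
}
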