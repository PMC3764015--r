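# Light schedules, timed parameter-override epochs, and protocol compilation.

#' Daily light schedule
#'
#' A repeating 24-h light schedule given as ordered segments of clock time
#' (hours since midnight). Segments must tile \[0, 24\] without overlap.
#'
#' @param segments data.frame with columns `start_h`, `end_h`, `lux`.
#' @return object of class `light_schedule`.
#' @seealso [ld_cycle()], [constant_light()], [darkness()]
#' @export
light_schedule <- function(segments) {
  stopifnot(is.data.frame(segments),
            all(c("start_h", "end_h", "lux") %in% names(segments)))
  segments <- segments[order(segments$start_h), , drop = FALSE]
  if (any(segments$lux < 0)) stop("lux must be nonnegative", call. = FALSE)
  if (segments$start_h[1] != 0 ||
      segments$end_h[nrow(segments)] != 24 ||
      any(abs(segments$end_h[-nrow(segments)] -
              segments$start_h[-1]) > 1e-9)) {
    stop("segments must cover 0-24 h without gaps or overlap", call. = FALSE)
  }
  structure(list(segments = segments), class = "light_schedule")
}

#' Standard light/dark cycle
#'
#' @param lights_on_h,lights_off_h clock times (h) of lights on/off.
#' @param lux photopic illuminance during the light phase.
#' @param dark_lux illuminance during the dark phase (default 0).
#' @return `light_schedule`.
#' @export
ld_cycle <- function(lights_on_h = 8, lights_off_h = 20, lux = 100,
                     dark_lux = 0) {
  stopifnot(lights_on_h >= 0, lights_off_h > lights_on_h, lights_off_h <= 24)
  seg <- data.frame(
    start_h = c(0, lights_on_h, lights_off_h),
    end_h = c(lights_on_h, lights_off_h, 24),
    lux = c(dark_lux, lux, dark_lux)
  )
  light_schedule(seg[seg$start_h < seg$end_h, , drop = FALSE])
}

#' Constant light (LL)
#' @param lux constant illuminance.
#' @return `light_schedule`.
#' @export
constant_light <- function(lux = 500) {
  light_schedule(data.frame(start_h = 0, end_h = 24, lux = lux))
}

#' Constant darkness (DD)
#' @return `light_schedule`.
#' @export
darkness <- function() constant_light(0)

#' Evaluate a schedule at a time point
#'
#' @param schedule a `light_schedule`.
#' @param t_s simulation time in seconds (vectorized); the schedule repeats
#'   every 24 h.
#' @return illuminance (lux).
#' @export
schedule_lux <- function(schedule, t_s) {
  stopifnot(inherits(schedule, "light_schedule"))
  hod <- (t_s / 3600) %% 24
  seg <- schedule$segments
  idx <- findInterval(hod, seg$start_h, rightmost.closed = FALSE)
  idx[idx < 1] <- 1
  seg$lux[idx]
}

#' Timed parameter-override epoch
#'
#' An epoch applies flat parameter overrides (see [apply_overrides()]) and
#' optionally a different light schedule over an inclusive range of protocol
#' days (day 1 = first simulated day). Changes take effect instantaneously at
#' epoch boundaries and the base configuration is restored when the epoch
#' ends.
#'
#' @param start_day,end_day inclusive 1-based day range.
#' @param overrides named list of parameter overrides.
#' @param schedule optional `light_schedule` replacing the base schedule.
#' @param label optional label used in logs and provenance.
#' @return object of class `protocol_epoch`.
#' @export
protocol_epoch <- function(start_day, end_day, overrides = list(),
                           schedule = NULL, label = NULL) {
  stopifnot(start_day >= 1, end_day >= start_day)
  structure(list(start_day = as.integer(start_day),
                 end_day = as.integer(end_day),
                 overrides = overrides, schedule = schedule,
                 label = label),
            class = "protocol_epoch")
}

#' Experimental protocol
#'
#' Couples a base parameter set and base daily light schedule with an ordered,
#' non-overlapping list of override epochs.
#'
#' @param params base `model_params`.
#' @param schedule base `light_schedule`.
#' @param epochs list of [protocol_epoch()] objects (may be empty).
#' @param name protocol label for provenance.
#' @return object of class `protocol`.
#' @export
protocol <- function(params, schedule, epochs = list(), name = "custom") {
  stopifnot(inherits(params, "model_params"),
            inherits(schedule, "light_schedule"))
  if (length(epochs)) {
    stopifnot(all(vapply(epochs, inherits, TRUE, "protocol_epoch")))
    ord <- order(vapply(epochs, `[[`, 1L, "start_day"))
    epochs <- epochs[ord]
    s <- vapply(epochs, `[[`, 1L, "start_day")
    e <- vapply(epochs, `[[`, 1L, "end_day")
    if (any(s[-1] <= e[-length(e)])) {
      stop("protocol epochs must not overlap", call. = FALSE)
    }
  }
  structure(list(params = params, schedule = schedule, epochs = epochs,
                 name = name),
            class = "protocol")
}

# Resolve the configuration (params + schedule + epoch label) active on a
# given protocol day. Days outside any epoch use the base configuration.
.active_config <- function(proto, day) {
  for (ep in proto$epochs) {
    if (day >= ep$start_day && day <= ep$end_day) {
      return(list(
        params = apply_overrides(proto$params, ep$overrides),
        schedule = if (is.null(ep$schedule)) proto$schedule else ep$schedule,
        label = if (is.null(ep$label)) "epoch" else ep$label
      ))
    }
  }
  list(params = proto$params, schedule = proto$schedule, label = "base")
}

#' Compile a protocol into integrator segments
#'
#' Expands the daily schedules and epochs of a protocol into a contiguous
#' segment table (start s, end s, lux, parameter-set column) spanning the
#' burn-in plus the protocol, with one internal parameter vector per distinct
#' epoch configuration. Burn-in days replicate the day-1 configuration so the
#' recorded record starts in the protocol's initial condition. Time zero of
#' the returned table is the start of burn-in; the offset of protocol day 1
#' is stored in `t_offset_s`.
#'
#' @param proto a `protocol`.
#' @param duration_days number of protocol days to simulate.
#' @param burn_in_days discarded initial days, run under the day-1
#'   configuration.
#' @return list with `segments` (matrix), `params` (matrix, one column per
#'   configuration), `config_labels`, `t_offset_s`.
#' @export
compile_protocol <- function(proto, duration_days, burn_in_days = 0) {
  stopifnot(inherits(proto, "protocol"), duration_days >= 1)
  day_cfg <- c(rep(1L, burn_in_days), seq_len(duration_days))
  configs <- list()
  cfg_key <- character(0)
  seg_list <- vector("list", length(day_cfg))
  for (i in seq_along(day_cfg)) {
    cfg <- .active_config(proto, day_cfg[i])
    key <- paste(cfg$label,
                 paste(format(internal_param_vector(cfg$params), digits = 15),
                       collapse = ","),
                 paste(format(unlist(cfg$schedule$segments)), collapse = ","),
                 sep = "|")
    j <- match(key, cfg_key)
    if (is.na(j)) {
      configs[[length(configs) + 1L]] <- cfg
      cfg_key <- c(cfg_key, key)
      j <- length(configs)
    }
    seg <- cfg$schedule$segments
    day0 <- (i - 1) * 86400
    seg_list[[i]] <- cbind(day0 + seg$start_h * 3600,
                           day0 + seg$end_h * 3600,
                           seg$lux, j - 1L)
  }
  segments <- do.call(rbind, seg_list)
  colnames(segments) <- c("t_start_s", "t_end_s", "lux", "param_col")
  pm <- vapply(configs, function(cfg) internal_param_vector(cfg$params),
               numeric(length(.param_order)))
  list(segments = segments, params = pm,
       config_labels = vapply(configs, `[[`, "", "label"),
       t_offset_s = burn_in_days * 86400)
}

#' Degu running-wheel switching protocol
#'
#' 108-day protocol of temporal-niche switching in the degu: wheel access on
#' days 1-22 and 68-108, LD (30 lux, clock time 8-20) on days 1-88, DD from
#' day 89. The wheel's hypothesized physiological effect is a sign inversion
#' (magnitude preserved) of the SPZ circadian modulation `nu_spz` and/or the
#' masking gain `m_mask`:
#' * `"both"` inverts both (circadian signal and masking),
#' * `"circadian_only"` inverts only `nu_spz`,
#' * `"masking_only"` inverts only `m_mask`.
#'
#' @param hypothesis one of `"both"`, `"circadian_only"`, `"masking_only"`.
#' @param params base degu parameters, default [load_preset()] `"degu"`.
#' @return a 108-day `protocol`.
#' @export
build_degu_protocol <- function(hypothesis = c("both", "circadian_only",
                                               "masking_only"),
                                params = NULL) {
  hypothesis <- match.arg(hypothesis)
  if (is.null(params)) params <- load_preset("degu")$params
  ld <- ld_cycle(8, 20, lux = 30)
  wheel <- switch(hypothesis,
    both = list(nu_spz = -params$relay$nu_spz,
                m_mask = -params$relay$m_mask),
    circadian_only = list(nu_spz = -params$relay$nu_spz),
    masking_only = list(m_mask = -params$relay$m_mask)
  )
  protocol(
    params, ld,
    epochs = list(
      protocol_epoch(1, 22, wheel, label = "wheel_LD"),
      protocol_epoch(68, 88, wheel, label = "wheel_LD"),
      protocol_epoch(89, 108, wheel, schedule = darkness(),
                     label = "wheel_DD")
    ),
    name = paste0("degu_switch_", hypothesis)
  )
}

#' Squirrel-monkey SCN lesion protocol
#'
#' Constant light at 500 lux. An SCN lesion is modeled by setting the gain on
#' pacemaker output to zero (`scn_gain = 0`); no other parameter differs
#' between intact and lesioned configurations, and positive masking by light
#' is present in both.
#'
#' @param lesioned logical; simulate the SCN-lesioned animal?
#' @param params base parameters, default [load_preset()]
#'   `"squirrel_monkey"`.
#' @return a `protocol` (epoch-free; the lesion is applied to the base
#'   parameters).
#' @export
build_lesion_protocol <- function(lesioned = FALSE, params = NULL) {
  if (is.null(params)) params <- load_preset("squirrel_monkey")$params
  if (lesioned) params <- apply_overrides(params, list(scn_gain = 0))
  protocol(params, constant_light(500),
           name = if (lesioned) "scn_lesioned_LL" else "scn_intact_LL")
}
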