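# Model parameters: construction, validation, flattening for the C++ core.
#
# Subsystems follow the model wiring: sleep/wake switch (VLPO + MA voltages),
# homeostatic sleep drive, van der Pol circadian pacemaker with photic and
# non-photic inputs, retinal photoreceptor stage, and the SPZ/DMH relay plus
# direct light masking. Time constants are stored in their conventional units
# (chi_h and tau_c_h in hours, everything else in seconds) and converted to
# seconds in one place, internal_param_vector().

#' Construct a full model parameter set
#'
#' Returns the complete parameter set of the sleep/wake-circadian model,
#' optionally overriding any of the defaults. Defaults are the nominal values
#' of the underlying sleep-switch and circadian pacemaker model lineage
#' (suitable for a generic diurnal mammal); species presets refine them via
#' [load_preset()].
#'
#' @param switch_ list of sleep/wake switch parameters:
#'   * `Q_max` maximum firing rate (1/s), `theta` sigmoid midpoint (mV),
#'     `sigma` sigmoid width (mV);
#'   * `nu_vm`, `nu_mv` mutual-inhibition coupling strengths (mV s, both
#'     negative: VLPO <- MA and MA <- VLPO);
#'   * `nu_vh` gain of the homeostatic drive onto the VLPO (mV per H-unit);
#'   * `A_m` constant cholinergic/other drive to the MA (mV);
#'   * `tau_v`, `tau_m` voltage relaxation time constants (s);
#'   * `noise_sd` additive white-noise intensity on each voltage equation
#'     (mV s^-1/2).
#' @param homeostat list: `chi_h` homeostatic time constant (hours), `mu`
#'   production gain (H-units per unit MA firing rate integrated over 1 s).
#' @param pacemaker list: `tau_c_h` intrinsic circadian period (hours);
#'   `mu_vdp`, `q`, `k`, `f_corr` van der Pol stiffness/forcing coefficients;
#'   `rho_np` non-photic drive strength and `np_wake`, `np_sleep` the two
#'   state-dependent levels; `r_np` steepness of the phase gate.
#' @param photic list: `alpha_0` activation-rate scale (1/s), `p` power-law
#'   exponent, `I_0` and `I_1` reference irradiances (lux), `beta` ready-state
#'   recovery rate (1/s), `G` photic drive gain, `b` circadian
#'   phase-modulation coefficient, `eye_closure_factor` multiplier on
#'   environmental lux during sleep (0 = complete gating), `masking_mode`
#'   either "photoreceptor" or "lux", `I_ref` reference lux for the masking
#'   signal.
#' @param relay list: `nu_spz` SPZ modulation factor in \[-1, 1\] (-1 nocturnal,
#'   +1 diurnal), `c_offset` mean offset of the relayed circadian signal,
#'   `g_dmh_vlpo` DMH/VLPO relay gain (drive to VLPO is `-g_dmh_vlpo` times
#'   the relayed signal, so a high signal promotes wake), `g_dmh_lha` DMH/LHA
#'   relay gain onto the MA (positive = cooperative/excitatory, negative =
#'   competitive/inhibitory), `m_mask` masking gain (positive = excites VLPO =
#'   negative masking; negative = wake-promoting = positive masking),
#'   `scn_gain` multiplier on pacemaker output (1 intact, 0 lesioned).
#' @param wake_threshold MA firing rate (1/s) above which the model is scored
#'   awake; wake requires strict exceedance.
#'
#' @return An object of class `model_params`: a named list of subsystem lists.
#' @examples
#' p <- model_params(relay = list(nu_spz = -1))
#' p$relay$nu_spz
#' @export
model_params <- function(switch_ = list(), homeostat = list(),
                         pacemaker = list(), photic = list(),
                         relay = list(), wake_threshold = 1) {
  p <- list(
    switch_ = modifyList(list(
      Q_max = 100, theta = 10, sigma = 3,
      nu_vm = -2.1, nu_mv = -1.8, nu_vh = 1.0,
      A_m = 1.3, tau_v = 10, tau_m = 10, noise_sd = 0
    ), switch_),
    homeostat = modifyList(list(chi_h = 45, mu = 4.4), homeostat),
    pacemaker = modifyList(list(
      tau_c_h = 24.2, mu_vdp = 0.13, q = 1 / 3, k = 0.55, f_corr = 0.99669,
      rho_np = 0.032, np_wake = 1 / 3, np_sleep = -2 / 3, r_np = 10
    ), pacemaker),
    photic = modifyList(list(
      alpha_0 = 0.05 / 60, p = 0.5, I_0 = 9500, I_1 = 100,
      beta = 0.0075 / 60, G = 37 * 60, b = 0.4,
      eye_closure_factor = 0, masking_mode = "photoreceptor", I_ref = 100
    ), photic),
    relay = modifyList(list(
      nu_spz = 1, c_offset = 0, g_dmh_vlpo = 2.9, g_dmh_lha = 0,
      m_mask = 0, scn_gain = 1, relay_phase_h = 0
    ), relay),
    wake_threshold = wake_threshold
  )
  class(p) <- "model_params"
  validate_params(p)
  p
}

#' Validate a model parameter set
#'
#' Checks ranges and sign conventions; called by [model_params()] and again
#' before every simulation so that protocol overrides cannot smuggle in
#' invalid values.
#'
#' @param p a `model_params` object.
#' @return `p`, invisibly, if valid; otherwise an error.
#' @export
validate_params <- function(p) {
  stopifnot(inherits(p, "model_params"))
  sw <- p$switch_
  chk <- function(ok, msg) if (!isTRUE(ok)) stop(msg, call. = FALSE)
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  for (blk in c("switch_", "homeostat", "pacemaker", "relay")) {
    vals <- p[[blk]]
    for (nm in names(vals)) {
      chk(num1(vals[[nm]]), sprintf("parameter %s$%s must be a finite number",
                                    blk, nm))
    }
  }
  chk(sw$Q_max > 0, "Q_max must be positive")
  chk(sw$sigma > 0, "sigma must be positive")
  chk(sw$tau_v > 0 && sw$tau_m > 0, "voltage time constants must be positive")
  chk(sw$nu_vm < 0 && sw$nu_mv < 0,
      "nu_vm and nu_mv must be negative (mutual inhibition)")
  chk(sw$noise_sd >= 0, "noise_sd must be nonnegative")
  chk(p$homeostat$chi_h > 0, "chi_h must be positive")
  chk(p$homeostat$mu > 0, "mu must be positive")
  chk(p$pacemaker$tau_c_h > 0, "tau_c_h must be positive")
  ph <- p$photic
  for (nm in c("alpha_0", "p", "I_0", "I_1", "beta", "G", "b",
               "eye_closure_factor", "I_ref")) {
    chk(num1(ph[[nm]]), sprintf("photic parameter %s must be a finite number", nm))
  }
  chk(ph$beta > 0, "beta must be positive")
  chk(ph$eye_closure_factor >= 0 && ph$eye_closure_factor <= 1,
      "eye_closure_factor must lie in [0, 1]")
  chk(ph$masking_mode %in% c("photoreceptor", "lux"),
      "masking_mode must be 'photoreceptor' or 'lux'")
  chk(ph$I_ref > 0, "I_ref must be positive")
  rl <- p$relay
  chk(rl$nu_spz >= -1 && rl$nu_spz <= 1, "nu_spz must lie in [-1, 1]")
  chk(rl$scn_gain >= 0 && rl$scn_gain <= 1, "scn_gain must lie in [0, 1]")
  chk(num1(p$wake_threshold) && p$wake_threshold > 0,
      "wake_threshold must be positive")
  invisible(p)
}

# Flat parameter layout shared with src/integrator.cpp. Order matters: the
# C++ enum indexes into this vector. masking_mode is encoded 0/1.
.param_order <- c(
  "Q_max", "theta", "sigma", "nu_vm", "nu_mv", "nu_vh", "A_m",
  "tau_v", "tau_m", "noise_sd",
  "chi_h", "mu",
  "tau_c_h", "mu_vdp", "q", "k", "f_corr", "rho_np", "np_wake", "np_sleep",
  "r_np",
  "alpha_0", "p", "I_0", "I_1", "beta", "G", "b", "eye_closure_factor",
  "nu_spz", "c_offset", "g_dmh_vlpo", "g_dmh_lha", "m_mask", "scn_gain",
  "relay_phase_h", "masking_mode", "I_ref", "wake_threshold"
)

#' Flatten parameters to the internal numeric vector
#'
#' Centralized unit conversion point: hour-valued constants stay in hours in
#' the vector (the core converts with a single 3600 factor), and
#' `masking_mode` is encoded numerically (0 = photoreceptor, 1 = lux).
#' Exported mainly for testing and provenance snapshots.
#'
#' @param p a `model_params` object.
#' @return named numeric vector in the fixed internal order.
#' @export
internal_param_vector <- function(p) {
  validate_params(p)
  v <- c(
    unlist(p$switch_),
    unlist(p$homeostat),
    unlist(p$pacemaker),
    unlist(p$photic[c("alpha_0", "p", "I_0", "I_1", "beta", "G", "b",
                      "eye_closure_factor")]),
    unlist(p$relay),
    masking_mode = if (identical(p$photic$masking_mode, "lux")) 1 else 0,
    I_ref = p$photic$I_ref,
    wake_threshold = p$wake_threshold
  )
  names(v) <- sub("^(switch_|homeostat|pacemaker|photic|relay)\\.", "", names(v))
  v <- v[.param_order]
  stopifnot(!anyNA(v))
  v
}

#' Apply flat parameter overrides
#'
#' Protocol epochs describe changes as flat `name = value` pairs (e.g.
#' `nu_spz = -1`, `scn_gain = 0`, `chi_h = 11`). This maps each name to its
#' subsystem slot and returns the updated, re-validated parameter set.
#'
#' @param p a `model_params` object.
#' @param overrides named list of scalar parameter values.
#' @return updated `model_params`.
#' @export
apply_overrides <- function(p, overrides) {
  if (length(overrides) == 0) return(p)
  stopifnot(!is.null(names(overrides)), all(nzchar(names(overrides))))
  for (nm in names(overrides)) {
    slot <- NULL
    for (blk in c("switch_", "homeostat", "pacemaker", "photic", "relay")) {
      if (nm %in% names(p[[blk]])) slot <- blk
    }
    if (!is.null(slot)) {
      p[[slot]][[nm]] <- overrides[[nm]]
    } else if (nm == "wake_threshold") {
      p$wake_threshold <- overrides[[nm]]
    } else {
      stop("unknown parameter override: ", nm, call. = FALSE)
    }
  }
  validate_params(p)
  p
}

#' @export
print.model_params <- function(x, ...) {
  cat("<model_params>\n")
  for (blk in c("switch_", "homeostat", "pacemaker", "photic", "relay")) {
    vals <- x[[blk]]
    cat(" ", sub("_$", "", blk), ": ",
        paste(sprintf("%s=%s", names(vals), vapply(vals, format, "")),
              collapse = ", "), "\n", sep = "")
  }
  cat("  wake_threshold:", x$wake_threshold, "s^-1\n")
  invisible(x)
}
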