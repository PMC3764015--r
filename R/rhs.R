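# Right-hand sides of the model, as pure R functions.
#
# These mirror the compiled integrator core exactly (a consistency test holds
# the two together) and exist so that each subsystem can be inspected and
# tested in isolation. State units: voltages mV, H in H-units, (x, x_c)
# dimensionless pacemaker pair, n in [0, 1]; all derivatives are per second.

#' Population firing rate
#'
#' Saturating sigmoid converting mean cell-body voltage to mean firing rate,
#' used for both the VLPO and MA populations.
#'
#' @param V mean cell-body voltage (mV); may be a vector.
#' @param p a `model_params` object (only the switch block is used).
#' @return firing rate(s) in (0, Q_max), 1/s.
#' @export
firing_rate <- function(V, p) {
  if (!all(is.finite(V))) stop("non-finite voltage", call. = FALSE)
  s <- p$switch_
  s$Q_max / (1 + exp(-(V - s$theta) / s$sigma))
}

#' Homeostatic sleep drive derivative
#'
#' H relaxes toward `mu * Q_m` with time constant `chi_h` (hours): it
#' saturates approximately exponentially during wake (high Q_m) and decays
#' approximately exponentially during sleep (Q_m near zero).
#'
#' @param H current homeostatic drive (H-units).
#' @param Q_m MA firing rate (1/s).
#' @param p `model_params`.
#' @return dH/dt in H-units per second.
#' @export
homeostat_rhs <- function(H, Q_m, p) {
  chi_s <- p$homeostat$chi_h * 3600
  if (chi_s <= 0) stop("chi_h must be positive", call. = FALSE)
  (p$homeostat$mu * Q_m - H) / chi_s
}

#' Pacemaker output function
#'
#' Maps the pacemaker state to the nonnegative, approximately unit-normalized
#' SCN output C0 = (1 + x_lag) / 2, where `x_lag` is the (x, x_c) pair
#' rotated by `relay_phase_h` hours: on the near-harmonic limit cycle this
#' reproduces x delayed by the multisynaptic SPZ/DMH transmission lag
#' (default 0). Configurable hook: pass a different function as `C0_fun` to
#' [relay_drive()] (the compiled core uses this default form).
#'
#' @param x,x_c pacemaker state pair.
#' @param phase_h relay transmission lag (h).
#' @param tau_c_h circadian period used to convert the lag to an angle (h).
#' @return SCN output, about \[0, 1\] on the limit cycle.
#' @export
pacemaker_output <- function(x, x_c = 0, phase_h = 0, tau_c_h = 24.2) {
  phi <- 2 * pi * phase_h / tau_c_h
  (1 + cos(phi) * x - sin(phi) * x_c) / 2
}

#' SPZ/DMH relay drives
#'
#' The SCN output `C = scn_gain * C0(x, x_c)` is modulated at the SPZ and
#' offset, giving the relayed signal `s = c_offset + nu_spz * C`. The DMH
#' forwards it to the VLPO (inhibition when the signal is high, hence
#' wake-promoting) and to the MA via the orexinergic LHA (sign of
#' `g_dmh_lha` sets cooperative vs. competitive action). Both drives are
#' affine in C.
#'
#' @param state named list or vector with `x` and `x_c` (a bare number is
#'   taken as `x` with `x_c = 0`).
#' @param p `model_params`.
#' @param C0_fun pacemaker output function, default [pacemaker_output()].
#' @return list with `drive_to_vlpo` and `drive_to_ma` (mV).
#' @export
relay_drive <- function(state, p, C0_fun = NULL) {
  if (is.numeric(state)) state <- list(x = state, x_c = 0)
  r <- p$relay
  C0 <- if (is.null(C0_fun)) {
    pacemaker_output(state$x, state$x_c, r$relay_phase_h,
                     p$pacemaker$tau_c_h)
  } else {
    C0_fun(state$x, state$x_c)
  }
  s_rel <- r$c_offset + r$nu_spz * r$scn_gain * C0
  list(drive_to_vlpo = -r$g_dmh_vlpo * s_rel,
       drive_to_ma = r$g_dmh_lha * s_rel)
}

#' Masking signal from ambient light
#'
#' Normalized monotone signal f(I) with f(0) = 0. In "photoreceptor" mode
#' (default) the masking pathway reuses the compressive retinal activation
#' nonlinearity alpha(I), scaled to 1 at `I_ref`; in "lux" mode it is simply
#' I / I_ref. The masking pathway responds to ambient light in both arousal
#' states: eye-closure gating applies only to the pacemaker's phase-resetting
#' input (gating the masking input through the scored arousal state couples
#' the drive discontinuously to the wake flag and can collapse the switch
#' hysteresis).
#'
#' @param I ambient illuminance (lux).
#' @param p `model_params`.
#' @return dimensionless masking signal, >= 0.
#' @export
masking_signal <- function(I, p) {
  if (any(I < 0)) stop("illuminance must be nonnegative", call. = FALSE)
  if (identical(p$photic$masking_mode, "lux")) {
    I / p$photic$I_ref
  } else {
    photic_alpha(I, p) / photic_alpha(p$photic$I_ref, p)
  }
}

#' Masking drive to the VLPO
#'
#' `m_mask * f(I)`: positive `m_mask` excites the sleep-promoting VLPO
#' (negative masking, light suppresses activity); negative `m_mask` inhibits
#' it (positive masking, light promotes wake).
#'
#' @inheritParams masking_signal
#' @return drive to the VLPO (mV).
#' @export
masking_drive <- function(I, p) {
  p$relay$m_mask * masking_signal(I, p)
}

#' Photoreceptor activation rate
#'
#' alpha(I) = alpha_0 * (I / I_0)^p * I / (I + I_1): a compressive power law
#' with an additional saturable factor; zero in darkness and strictly
#' increasing in I.
#'
#' @param I illuminance (lux).
#' @param p `model_params`.
#' @return activation rate, 1/s.
#' @export
photic_alpha <- function(I, p) {
  if (any(I < 0)) stop("illuminance must be nonnegative", call. = FALSE)
  ph <- p$photic
  ifelse(I > 0, ph$alpha_0 * (I / ph$I_0)^ph$p * I / (I + ph$I_1), 0)
}

#' Photoreceptor pool derivative
#'
#' dn/dt = alpha * (1 - n) - beta * n; ready receptors are activated at rate
#' alpha and recover at rate beta, so n equilibrates at alpha / (alpha + beta)
#' and stays in \[0, 1\].
#'
#' @param n activated fraction, in \[0, 1\].
#' @param alpha activation rate (1/s), from [photic_alpha()].
#' @param p `model_params`.
#' @return dn/dt, 1/s.
#' @export
photoreceptor_rhs <- function(n, alpha, p) {
  if (any(n < 0 | n > 1)) stop("n must lie in [0, 1]", call. = FALSE)
  alpha * (1 - n) - p$photic$beta * n
}

#' Photic drive to the circadian pacemaker
#'
#' B = G * alpha(I_eff) * (1 - n) * (1 - b x)(1 - b x_c): proportional to the
#' photoreceptor activation rate and modulated by circadian phase (the SCN is
#' more light-sensitive at some phases). During scored sleep the environmental
#' lux is attenuated by `eye_closure_factor` (default 0: eyes closed see no
#' light).
#'
#' @param state named list or vector with `x`, `x_c`, `n`.
#' @param awake logical arousal state.
#' @param I environmental illuminance (lux).
#' @param p `model_params`.
#' @return photic drive B (dimensionless pacemaker forcing).
#' @export
circadian_light_drive <- function(state, awake, I, p) {
  I_eff <- if (awake) I else p$photic$eye_closure_factor * I
  ph <- p$photic
  ph$G * photic_alpha(I_eff, p) * (1 - state$n) *
    (1 - ph$b * state$x) * (1 - ph$b * state$x_c)
}

#' Non-photic drive to the circadian pacemaker
#'
#' Two-level, state-dependent drive N = rho_np * s * (1 - tanh(r_np x)) with
#' s = np_wake during wake and s = np_sleep during sleep. At preset strength
#' its effect is small compared with light.
#'
#' @param awake logical arousal state.
#' @param state named list or vector with `x`.
#' @param p `model_params`.
#' @return non-photic drive N (dimensionless pacemaker forcing).
#' @export
nonphotic_drive <- function(awake, state, p) {
  pc <- p$pacemaker
  lev <- if (awake) pc$np_wake else pc$np_sleep
  pc$rho_np * lev * (1 - tanh(pc$r_np * state$x))
}

#' Circadian pacemaker derivatives
#'
#' Modified van der Pol oscillator in the (x, x_c) plane with a stiffening
#' seventh-order conservative term, forced by the photic drive B and
#' non-photic drive N. With B = N = 0 it settles on a stable limit cycle
#' whose period is within 1% of `tau_c_h`.
#'
#' @param state named list or vector with `x`, `x_c`.
#' @param B photic drive.
#' @param N non-photic drive.
#' @param p `model_params`.
#' @return list with `dx` and `dx_c`, per second.
#' @export
pacemaker_rhs <- function(state, B, N, p) {
  pc <- p$pacemaker
  kap <- pi / (12 * 3600)
  x <- state$x
  x_c <- state$x_c
  stiff <- pc$mu_vdp * (x / 3 + 4 * x^3 / 3 - 256 * x^7 / 105)
  om <- 24 / (pc$f_corr * pc$tau_c_h)
  list(
    dx = kap * (x_c + stiff + B + N),
    dx_c = kap * (pc$q * B * x_c - x * (om^2 + pc$k * B))
  )
}

#' Full composed model derivative
#'
#' Assembles all subsystem right-hand sides at one state and time. The wake
#' flag is computed from the MA firing rate (strict exceedance of the wake
#' threshold) and feeds back into eye-closure light gating and the non-photic
#' drive. Drives: D_v = nu_vh H + relay-to-VLPO + masking;
#' D_m = A_m + relay-to-MA.
#'
#' @param state named list with `V_v`, `V_m`, `H`, `x`, `x_c`, `n`.
#' @param t simulation time (s), used to evaluate the light schedule.
#' @param p `model_params`.
#' @param schedule a `light_schedule` (or compiled protocol) evaluated at `t`.
#' @return named list of derivatives (`dV_v`, `dV_m`, `dH`, `dx`, `dx_c`,
#'   `dn`) plus the diagnostic entries `Q_v`, `Q_m`, `awake`, `I`, `B`.
#' @export
full_rhs <- function(state, t, p, schedule) {
  I <- schedule_lux(schedule, t)
  Q_m <- firing_rate(state$V_m, p)
  Q_v <- firing_rate(state$V_v, p)
  awake <- Q_m > p$wake_threshold
  I_eff <- if (awake) I else p$photic$eye_closure_factor * I
  rel <- relay_drive(state, p)
  D_v <- p$switch_$nu_vh * state$H + rel$drive_to_vlpo +
    masking_drive(I, p)
  D_m <- p$switch_$A_m + rel$drive_to_ma
  B <- circadian_light_drive(state, awake, I, p)
  N <- nonphotic_drive(awake, state, p)
  pace <- pacemaker_rhs(state, B, N, p)
  list(
    dV_v = (-state$V_v + p$switch_$nu_vm * Q_m + D_v) / p$switch_$tau_v,
    dV_m = (-state$V_m + p$switch_$nu_mv * Q_v + D_m) / p$switch_$tau_m,
    dH = homeostat_rhs(state$H, Q_m, p),
    dx = pace$dx,
    dx_c = pace$dx_c,
    dn = photoreceptor_rhs(state$n, photic_alpha(I_eff, p), p),
    Q_v = Q_v, Q_m = Q_m, awake = awake, I = I, B = B
  )
}
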