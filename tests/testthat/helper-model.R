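# Shared helpers: small parameter sets and synthetic series used across the
# unit tests. Everything is generated in code; no stored fixtures.

quick_cfg <- function(seed = 1, burn_in_days = 0, dt = 1,
                      record_stride_s = 30) {
  integrator_config(dt = dt, seed = seed, burn_in_days = burn_in_days,
                    record_stride_s = record_stride_s)
}

# deterministic parameter set with the pacemaker decoupled from behavior
decoupled_pacemaker_params <- function(tau_c_h = 24.2) {
  model_params(
    switch_ = list(noise_sd = 0),
    pacemaker = list(tau_c_h = tau_c_h, rho_np = 0),
    relay = list(scn_gain = 1)
  )
}

# mean interval between upward zero crossings of x, in hours
x_period_h <- function(sim) {
  x <- sim$trace$x
  t <- sim$trace$time_s
  up <- which(x[-1] > 0 & x[-length(x)] <= 0)
  # linear interpolation of each crossing time
  tc <- t[up] + (t[up + 1] - t[up]) * (-x[up]) / (x[up + 1] - x[up])
  mean(diff(tc)) / 3600
}

# synthetic Q_m series with one sleep block per cycle of the given period
synthetic_monophasic_qm <- function(period_h, n_cycles, sleep_h = 8,
                                    dt_s = 60, q_wake = 5, q_sleep = 0.1) {
  total_s <- period_h * 3600 * n_cycles
  t <- seq(0, total_s - dt_s, by = dt_s)
  phase_h <- (t / 3600) %% period_h
  ifelse(phase_h < sleep_h, q_sleep, q_wake)
}
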