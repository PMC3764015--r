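p0 <- model_params()

test_that("firing-rate sigmoid has the right midpoint, saturation and shape", {
  sw <- p0$switch_
  expect_equal(firing_rate(sw$theta, p0), sw$Q_max / 2)
  expect_equal(firing_rate(-1e6, p0), 0, tolerance = 1e-12)
  expect_equal(firing_rate(1e6, p0), sw$Q_max)
  # closed form: V = theta + sigma ln 3 gives 3/4 of Q_max
  expect_equal(firing_rate(sw$theta + sw$sigma * log(3), p0),
               0.75 * sw$Q_max)
  V <- seq(-40, 60, by = 0.5)
  Q <- firing_rate(V, p0)
  expect_true(all(diff(Q) > 0))
  expect_true(all(Q > 0 & Q < sw$Q_max))
  expect_error(firing_rate(NaN, p0), "non-finite")
})

test_that("homeostat relaxes exponentially and has fixed point mu*Q_m", {
  chi_s <- p0$homeostat$chi_h * 3600
  # homogeneous decay: dH/dt = -H/chi
  expect_equal(homeostat_rhs(7, 0, p0), -7 / chi_s)
  # fixed point
  expect_equal(homeostat_rhs(p0$homeostat$mu * 4, 4, p0), 0)
  # forward-Euler solution tracks the closed form H0 * exp(-t/chi)
  H <- 10
  dt <- 10
  for (i in 1:360) H <- H + dt * homeostat_rhs(H, 0, p0)
  expect_equal(H, 10 * exp(-3600 / chi_s), tolerance = 1e-4)
})

test_that("relay drives are affine in C with slope set by nu_spz", {
  p <- model_params(relay = list(nu_spz = 0.6, c_offset = 0.3,
                                 g_dmh_vlpo = 4, g_dmh_lha = -1.5))
  xs <- seq(-1, 1, by = 0.25)
  dv <- vapply(xs, function(x) relay_drive(x, p)$drive_to_vlpo, 1)
  dm <- vapply(xs, function(x) relay_drive(x, p)$drive_to_ma, 1)
  # finite differences constant (affine)
  expect_equal(diff(dv), rep(diff(dv)[1], length(dv) - 1), tolerance = 1e-12)
  expect_equal(diff(dm), rep(diff(dm)[1], length(dm) - 1), tolerance = 1e-12)
  # slope proportional to nu_spz (dC/dx = 1/2)
  expect_equal(diff(dv)[1] / 0.25, -4 * 0.6 * 0.5, tolerance = 1e-12)
})

test_that("relay lesion and mirror-symmetry behave as specified", {
  lesioned <- model_params(relay = list(scn_gain = 0, nu_spz = 1,
                                        c_offset = 0.4, g_dmh_vlpo = 3,
                                        g_dmh_lha = 1))
  d1 <- relay_drive(-0.9, lesioned)
  d2 <- relay_drive(0.9, lesioned)
  expect_equal(d1, d2)  # independent of pacemaker state
  expect_equal(d1$drive_to_vlpo, -3 * 0.4)
  # +nu and -nu drives mirror about the nu = 0 drive
  mk <- function(nu) model_params(relay = list(nu_spz = nu, c_offset = 0.4,
                                               g_dmh_vlpo = 3))
  x <- 0.37
  v0 <- relay_drive(x, mk(0))$drive_to_vlpo
  vp <- relay_drive(x, mk(0.8))$drive_to_vlpo
  vm <- relay_drive(x, mk(-0.8))$drive_to_vlpo
  expect_equal(vp - v0, -(vm - v0), tolerance = 1e-12)
})

test_that("relay phase lag delays the pacemaker output on the limit cycle", {
  # x = cos(theta), x_c = -sin(theta): a lag of tau_c/4 must reproduce x a
  # quarter cycle earlier
  th <- seq(0, 2 * pi, length.out = 97)[-97]
  x <- cos(th)
  xc <- -sin(th)
  lagged <- pacemaker_output(x, xc, phase_h = 24.2 / 4, tau_c_h = 24.2)
  direct <- (1 + cos(th - pi / 2)) / 2
  expect_equal(lagged, direct, tolerance = 1e-10)
})

test_that("masking drive is zero in darkness, sign-symmetric, monotone", {
  p <- model_params(relay = list(m_mask = 2))
  expect_equal(masking_drive(0, p), 0)
  expect_gt(masking_drive(100, p), 0)  # positive m_mask = sleep-promoting
  pneg <- model_params(relay = list(m_mask = -2))
  expect_equal(masking_drive(50, pneg), -masking_drive(50, p))
  f <- masking_signal(c(1, 10, 30, 100, 500), p)
  expect_true(all(diff(f) > 0))
  expect_error(masking_drive(-1, p), "nonnegative")
  # the linear-lux alternative
  plux <- model_params(photic = list(masking_mode = "lux"),
                       relay = list(m_mask = 1))
  expect_equal(masking_drive(150, plux), 150 / plux$photic$I_ref)
})

test_that("photoreceptor activation rate matches direct substitution", {
  ph <- p0$photic
  expect_equal(photic_alpha(0, p0), 0)
  expect_gt(photic_alpha(100, p0), photic_alpha(30, p0))
  expect_gt(photic_alpha(30, p0), 0)
  # independent evaluation of the printed functional form at I_0
  direct <- ph$alpha_0 * (ph$I_0 / ph$I_0)^ph$p * ph$I_0 / (ph$I_0 + ph$I_1)
  expect_equal(photic_alpha(ph$I_0, p0), direct)
  expect_error(photic_alpha(-5, p0), "nonnegative")
})

test_that("photoreceptor pool has equilibrium alpha/(alpha+beta) and stays in [0,1]", {
  a <- photic_alpha(200, p0)
  b <- p0$photic$beta
  expect_equal(photoreceptor_rhs(a / (a + b), a, p0), 0, tolerance = 1e-18)
  # dark recovery: pure exponential decay at rate beta
  expect_equal(photoreceptor_rhs(0.5, 0, p0), -b * 0.5)
  # step from darkness: relaxation to n* with time constant 1/(alpha+beta),
  # checked against the closed-form first-order solution
  n <- 0
  dt <- 10
  steps <- 2000
  for (i in seq_len(steps)) n <- n + dt * photoreceptor_rhs(n, a, p0)
  tt <- dt * steps
  closed <- a / (a + b) * (1 - exp(-(a + b) * tt))
  expect_equal(n, closed, tolerance = 1e-3)
  expect_error(photoreceptor_rhs(1.2, a, p0), "\\[0, 1\\]")
})

test_that("photic drive to the pacemaker is gated as specified", {
  st <- list(x = 0.2, x_c = -0.5, n = 0.3)
  expect_equal(circadian_light_drive(st, TRUE, 0, p0), 0)
  # asleep with complete eye closure sees no light
  expect_equal(circadian_light_drive(st, FALSE, 1e4, p0), 0)
  # all receptors activated -> no drive
  expect_equal(circadian_light_drive(list(x = 0, x_c = 0, n = 1), TRUE,
                                     500, p0), 0)
  expect_gt(circadian_light_drive(st, TRUE, 500, p0), 0)
  # partial eyelid transmission
  pecf <- model_params(photic = list(eye_closure_factor = 0.2))
  expect_gt(circadian_light_drive(st, FALSE, 500, pecf), 0)
})

test_that("non-photic drive is a two-level switch scaled by rho_np", {
  st <- list(x = 0.1)
  off <- model_params(pacemaker = list(rho_np = 0))
  expect_equal(nonphotic_drive(TRUE, st, off), 0)
  expect_equal(nonphotic_drive(FALSE, st, off), 0)
  nw <- nonphotic_drive(TRUE, st, p0)
  ns <- nonphotic_drive(FALSE, st, p0)
  expect_true(nw != ns)
  expect_equal(nw / p0$pacemaker$np_wake, ns / p0$pacemaker$np_sleep,
               tolerance = 1e-12)
})

test_that("unforced pacemaker period is within 1% of tau_c", {
  for (tau in c(23.0, 24.2, 25.2)) {
    sim <- simulate_model(decoupled_pacemaker_params(tau), 30,
                          quick_cfg(burn_in_days = 5), schedule = darkness())
    expect_equal(x_period_h(sim), tau, tolerance = 0.01)
  }
})

test_that("non-photic drive shifts the DD free-run by less than 0.5 h", {
  with_np <- model_params(switch_ = list(noise_sd = 0))
  base <- x_period_h(simulate_model(with_np, 25, quick_cfg(burn_in_days = 5),
                                    schedule = darkness()))
  no_np <- x_period_h(simulate_model(decoupled_pacemaker_params(24.2), 25,
                                     quick_cfg(burn_in_days = 5),
                                     schedule = darkness()))
  expect_lt(abs(base - no_np), 0.5)
})

test_that("full model derivative equals composition of subsystem parts", {
  set.seed(42)
  sched <- ld_cycle(8, 20, 100)
  p <- load_preset("degu")$params
  for (k in 1:10) {
    st <- list(V_v = runif(1, -15, 10), V_m = runif(1, -15, 10),
               H = runif(1, 0, 20), x = runif(1, -1.1, 1.1),
               x_c = runif(1, -1.1, 1.1), n = runif(1, 0, 1))
    t <- runif(1, 0, 86400 * 3)
    d <- full_rhs(st, t, p, sched)
    I <- schedule_lux(sched, t)
    Q_m <- firing_rate(st$V_m, p)
    Q_v <- firing_rate(st$V_v, p)
    awake <- Q_m > p$wake_threshold
    I_eff <- if (awake) I else p$photic$eye_closure_factor * I
    rel <- relay_drive(st, p)
    D_v <- p$switch_$nu_vh * st$H + rel$drive_to_vlpo + masking_drive(I, p)
    D_m <- p$switch_$A_m + rel$drive_to_ma
    expect_equal(d$dV_v, (-st$V_v + p$switch_$nu_vm * Q_m + D_v) /
                   p$switch_$tau_v)
    expect_equal(d$dV_m, (-st$V_m + p$switch_$nu_mv * Q_v + D_m) /
                   p$switch_$tau_m)
    expect_equal(d$dH, homeostat_rhs(st$H, Q_m, p))
    pr <- pacemaker_rhs(st, circadian_light_drive(st, awake, I, p),
                        nonphotic_drive(awake, st, p), p)
    expect_equal(d$dx, pr$dx)
    expect_equal(d$dx_c, pr$dx_c)
    expect_equal(d$dn, photoreceptor_rhs(st$n, photic_alpha(I_eff, p), p))
  }
})

test_that("deterministic switch is bistable for intermediate constant drive", {
  # freeze H influence and the circadian input; pick a drive inside the fold
  # window and integrate forward from wake-like and sleep-like states
  p <- model_params(switch_ = list(noise_sd = 0, nu_vh = 0),
                    relay = list(scn_gain = 0, c_offset = -0.69,
                                 g_dmh_vlpo = 2.9))
  run_from <- function(st0) {
    cfg <- quick_cfg()
    cfg$initial_state <- st0
    sim <- simulate_model(p, 1, cfg, schedule = darkness())
    tail(sim$trace$Q_m, 1)
  }
  q_wake <- run_from(c(V_v = -10, V_m = 0, H = 5, x = 0, x_c = 0, n = 0))
  q_sleep <- run_from(c(V_v = 5, V_m = -15, H = 5, x = 0, x_c = 0, n = 0))
  expect_gt(q_wake, 1)
  expect_lt(q_sleep, 1)
})

test_that("parameter validation enforces ranges and unit conversion is centralized", {
  expect_error(model_params(relay = list(nu_spz = 1.5)), "nu_spz")
  expect_error(model_params(switch_ = list(nu_vm = 0.5)), "mutual inhibition")
  expect_error(model_params(homeostat = list(chi_h = -1)), "chi_h")
  expect_error(model_params(photic = list(eye_closure_factor = 2)),
               "eye_closure_factor")
  v <- internal_param_vector(model_params(homeostat = list(chi_h = 45)))
  expect_equal(unname(v["chi_h"]), 45)  # stored in hours, converted in core
  expect_equal(unname(v["masking_mode"]), 0)
  expect_error(apply_overrides(model_params(), list(bogus = 1)), "unknown")
})
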