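// Euler-Maruyama core for the sleep/wake-circadian model.
//
// The model couples the VLPO/MA flip-flop voltages, the homeostatic drive H,
// the van der Pol pacemaker pair (x, x_c), and the photoreceptor fraction n.
// Additive Gaussian white noise enters the two voltage equations only, as
// noise_sd * sqrt(dt) * z per step, drawn from R's RNG so that set.seed()
// gives bit-identical trajectories.
//
// The light/parameter protocol arrives as a segment table (t_start, t_end,
// lux, param_column) with one parameter vector per distinct epoch
// configuration; segments are contiguous and traversed in order.

#include <Rcpp.h>
using namespace Rcpp;

// indices into the flat parameter vector; must match .param_order in
// R/params.R
enum ParIdx {
  P_QMAX, P_THETA, P_SIGMA, P_NUVM, P_NUMV, P_NUVH, P_AM,
  P_TAUV, P_TAUM, P_NOISE,
  P_CHI, P_MU,
  P_TAUC, P_MUVDP, P_Q, P_K, P_F, P_RHONP, P_NPW, P_NPS, P_RNP,
  P_ALPHA0, P_P, P_I0, P_I1, P_BETA, P_G, P_B, P_ECF,
  P_NUSPZ, P_COFF, P_GV, P_GL, P_MMASK, P_SCN, P_RPHI,
  P_MODE, P_IREF, P_WTHR,
  NPAR
};

static inline double qfire(double V, const double* p) {
  return p[P_QMAX] / (1.0 + std::exp(-(V - p[P_THETA]) / p[P_SIGMA]));
}

static inline double palpha(double I, const double* p) {
  if (I <= 0.0) return 0.0;
  return p[P_ALPHA0] * std::pow(I / p[P_I0], p[P_P]) * I / (I + p[P_I1]);
}

// [[Rcpp::export(name = ".em_integrate")]]
List em_integrate(NumericVector state0, double dt, double n_steps_d,
                  NumericMatrix segments, NumericMatrix params,
                  int record_stride) {
  if (state0.size() != 6) stop("state0 must have 6 elements");
  if (dt <= 0) stop("dt must be positive");
  if (record_stride < 1) stop("record_stride must be >= 1");
  if (params.nrow() != NPAR) stop("parameter matrix has wrong row count");
  const R_xlen_t n_steps = (R_xlen_t)n_steps_d;
  const int nseg = segments.nrow();
  if (nseg < 1) stop("empty segment table");

  double V_v = state0[0], V_m = state0[1], H = state0[2];
  double x = state0[3], x_c = state0[4], n = state0[5];

  const R_xlen_t n_rec = n_steps / record_stride + 1;
  NumericVector r_t(n_rec), r_Vv(n_rec), r_Vm(n_rec), r_H(n_rec),
      r_x(n_rec), r_xc(n_rec), r_n(n_rec), r_Qm(n_rec), r_Qv(n_rec),
      r_lux(n_rec);
  LogicalVector r_awake(n_rec);

  const double kap = M_PI / (12.0 * 3600.0);
  int seg = 0;
  R_xlen_t rec = 0;
  RNGScope rngscope;

  for (R_xlen_t i = 0; i <= n_steps; ++i) {
    const double t = i * dt;
    while (seg < nseg - 1 && t >= segments(seg, 1)) ++seg;
    const double I = segments(seg, 2);
    const int pc = (int)segments(seg, 3);
    if (pc < 0 || pc >= params.ncol()) stop("segment parameter index out of range");
    const double* p = &params(0, pc);

    const double Q_m = qfire(V_m, p);
    const double Q_v = qfire(V_v, p);
    const bool awake = Q_m > p[P_WTHR];
    const double I_eff = awake ? I : p[P_ECF] * I;

    if (i % record_stride == 0) {
      r_t[rec] = t; r_Vv[rec] = V_v; r_Vm[rec] = V_m; r_H[rec] = H;
      r_x[rec] = x; r_xc[rec] = x_c; r_n[rec] = n;
      r_Qm[rec] = Q_m; r_Qv[rec] = Q_v; r_awake[rec] = awake; r_lux[rec] = I;
      ++rec;
    }
    if (i == n_steps) break;

    const double al = palpha(I_eff, p);
    const double B = p[P_G] * al * (1.0 - n) *
        (1.0 - p[P_B] * x) * (1.0 - p[P_B] * x_c);
    const double Ns = p[P_RHONP] * (awake ? p[P_NPW] : p[P_NPS]) *
        (1.0 - std::tanh(p[P_RNP] * x));
    // pacemaker output as seen by the relay; relay_phase_h rotates the
    // (x, x_c) pair to model the multisynaptic SPZ/DMH transmission lag
    const double rphi = 2.0 * M_PI * p[P_RPHI] / p[P_TAUC];
    const double x_lag = std::cos(rphi) * x - std::sin(rphi) * x_c;
    const double C = p[P_SCN] * 0.5 * (1.0 + x_lag);
    // masking responds to ambient light in both arousal states (eye-closure
    // gating applies to the pacemaker's phase-resetting pathway only)
    const double s_rel = p[P_COFF] + p[P_NUSPZ] * C;
    double mask;
    if (p[P_MODE] < 0.5) {
      mask = p[P_MMASK] * palpha(I, p) / palpha(p[P_IREF], p);
    } else {
      mask = p[P_MMASK] * I / p[P_IREF];
    }

    const double D_v = p[P_NUVH] * H - p[P_GV] * s_rel + mask;
    const double D_m = p[P_AM] + p[P_GL] * s_rel;

    const double dVv = (-V_v + p[P_NUVM] * Q_m + D_v) / p[P_TAUV];
    const double dVm = (-V_m + p[P_NUMV] * Q_v + D_m) / p[P_TAUM];
    const double dH = (p[P_MU] * Q_m - H) / (p[P_CHI] * 3600.0);
    const double stiff = p[P_MUVDP] *
        (x / 3.0 + 4.0 * x * x * x / 3.0 -
         256.0 * std::pow(x, 7.0) / 105.0);
    const double om = 24.0 / (p[P_F] * p[P_TAUC]);
    const double dx = kap * (x_c + stiff + B + Ns);
    const double dxc = kap * (p[P_Q] * B * x_c - x * (om * om + p[P_K] * B));
    const double dn = al * (1.0 - n) - p[P_BETA] * n;

    const double sd = p[P_NOISE];
    if (sd > 0.0) {
      const double sq = std::sqrt(dt);
      V_v += dt * dVv + sd * sq * norm_rand();
      V_m += dt * dVm + sd * sq * norm_rand();
    } else {
      V_v += dt * dVv;
      V_m += dt * dVm;
    }
    H += dt * dH;
    x += dt * dx;
    x_c += dt * dxc;
    n += dt * dn;
    if (n < 0.0) n = 0.0; else if (n > 1.0) n = 1.0;

    if (!(R_FINITE(V_v) && R_FINITE(V_m) && R_FINITE(H) &&
          R_FINITE(x) && R_FINITE(x_c) && R_FINITE(n))) {
      const char* bad = !R_FINITE(V_v) ? "V_v" : !R_FINITE(V_m) ? "V_m" :
          !R_FINITE(H) ? "H" : !R_FINITE(x) ? "x" :
          !R_FINITE(x_c) ? "x_c" : "n";
      stop("non-finite state variable %s at step %td (t = %.1f s)",
           bad, (ptrdiff_t)(i + 1), t + dt);
    }
  }

  return List::create(
      _["time_s"] = r_t, _["V_v"] = r_Vv, _["V_m"] = r_Vm, _["H"] = r_H,
      _["x"] = r_x, _["x_c"] = r_xc, _["n"] = r_n,
      _["Q_m"] = r_Qm, _["Q_v"] = r_Qv, _["awake"] = r_awake,
      _["lux"] = r_lux);
}
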