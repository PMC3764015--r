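name: human_nominal
description: 'Nominal diurnal human: consolidated ~7.5-h nightly sleep under a 16:8
  indoor light day; circadian signal exclusively wake-promoting.'
params:
  switch_:
    Q_max: 100.0
    theta: 10.0
    sigma: 3.0
    nu_vm: -2.1
    nu_mv: -1.8
    nu_vh: 1.0
    A_m: 1.3
    tau_v: 10.0
    tau_m: 10.0
    noise_sd: 0.25
  homeostat:
    chi_h: 45.0
    mu: 4.4
  pacemaker:
    tau_c_h: 24.199999999999999
    mu_vdp: 0.13
    q: 0.333333333333333
    k: 0.55
    f_corr: 0.99669
    rho_np: 0.032
    np_wake: 0.333333333333333
    np_sleep: -0.666666666666667
    r_np: 10.0
  photic:
    alpha_0: 0.000833333333333
    p: 0.5
    I_0: 9500.0
    I_1: 100.0
    beta: 0.000125
    G: 2220.0
    b: 0.4
    eye_closure_factor: 0.0
    masking_mode: photoreceptor
    I_ref: 100.0
  relay:
    nu_spz: 1.0
    c_offset: 1.5
    g_dmh_vlpo: 8.0
    g_dmh_lha: 0.0
    m_mask: -0.5
    scn_gain: 1.0
    relay_phase_h: 0.0
  wake_threshold: 1.0
provenance:
  Q_max: lineage
  theta: lineage
  sigma: lineage
  nu_vm: lineage
  nu_mv: lineage
  nu_vh: lineage
  A_m: lineage
  tau_v: lineage
  tau_m: lineage
  noise_sd: fitted
  chi_h: fitted
  mu: lineage
  tau_c_h: fitted
  mu_vdp: lineage
  q: lineage
  k: lineage
  f_corr: lineage
  rho_np: lineage
  np_wake: lineage
  np_sleep: lineage
  r_np: lineage
  alpha_0: lineage
  p: lineage
  I_0: lineage
  I_1: lineage
  beta: lineage
  G: fitted
  b: lineage
  eye_closure_factor: convention
  masking_mode: convention
  I_ref: convention
  nu_spz: convention
  c_offset: fitted
  g_dmh_vlpo: fitted
  g_dmh_lha: fitted
  m_mask: fitted
  scn_gain: convention
  relay_phase_h: fitted
  wake_threshold: lineage
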