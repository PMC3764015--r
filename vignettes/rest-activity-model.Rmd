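---
title: "A physiologically based model of mammalian temporal niche"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A physiologically based model of mammalian temporal niche}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7)
library(nichesim)
```

## The model

`nichesim` simulates mammalian sleep/wake and rest/activity patterns from a
small network of hypothalamic populations:

* **Sleep/wake switch.** The wake-promoting monoaminergic (MA) population
  and the sleep-promoting ventrolateral preoptic area (VLPO) mutually
  inhibit each other. Each population carries a mean cell-body voltage
  $V_m$, $V_v$ (mV) obeying first-order dynamics
  $\tau\,\dot V_v = -V_v + \nu_{vm} Q_m + D_v + \xi_v$,
  $\tau\,\dot V_m = -V_m + \nu_{mv} Q_v + D_m + \xi_m$,
  with mean firing rates given by the sigmoid
  $Q(V) = Q_{\max}/(1 + e^{-(V-\theta)/\sigma})$, mutual-inhibition weights
  $\nu_{vm}, \nu_{mv} < 0$, and additive Gaussian white noise $\xi$ on the
  two voltage equations only. Because of the mutual inhibition the switch is
  bistable over a range of drives: for the default parameters the fold
  bifurcations sit at $D_v \approx 1.45$ and $2.50$ mV (at $D_m = A_m$),
  so transitions between wake and sleep are abrupt.
* **Homeostatic sleep drive.** $ \chi\,\dot H = \mu Q_m - H$: sleep
  pressure accumulates in proportion to MA firing during wake and decays
  during sleep, with time constant `chi_h` (hours). H excites the VLPO with
  gain `nu_vh`.
* **Circadian pacemaker.** The SCN is a modified van der Pol oscillator in
  the pair $(x, x_c)$ with intrinsic period `tau_c_h`, a seventh-order
  stiffening term, and forcing by a photic drive $B$ and a small two-level
  non-photic drive $N$ (different constants in wake and sleep). Its
  unforced period matches `tau_c_h` to within 1% (tested).
* **Photoreception.** Light of intensity $I$ (lux) activates ready
  photoreceptors at rate
  $\alpha(I) = \alpha_0 (I/I_0)^p\, I/(I + I_1)$; the activated fraction
  $n$ recovers at rate $\beta$. The pacemaker drive is
  $B = G\,\alpha(I_\mathrm{eff})(1-n)(1 - b x)(1 - b x_c)$, so the clock is
  more sensitive at some phases. During scored sleep the effective input is
  $I_\mathrm{eff} = \texttt{eye\_closure\_factor}\cdot I$ (default 0:
  closed eyes see no light).
* **SPZ/DMH relay.** The SCN output $C_0 = (1 + x_\mathrm{lag})/2$ is
  modulated at the subparaventricular zone by $\nu_\mathrm{spz} \in
  [-1, 1]$ ($-1$ nocturnal, $+1$ diurnal) and offset, giving the relayed
  signal $s = c_\mathrm{offset} + \nu_\mathrm{spz}\,C$ with
  $C = \texttt{scn\_gain}\cdot C_0$. The DMH forwards $-g_\mathrm{dmh\_vlpo}\,s$
  to the VLPO (wake-promoting when $s$ is high) and
  $g_\mathrm{dmh\_lha}\,s$ to the MA via the orexinergic LHA; the sign of
  `g_dmh_lha` makes the two relays cooperative or competitive.
* **Masking.** Light also acts directly on the VLPO with drive
  $m_\mathrm{mask}\, f(I)$, $f(I) = \alpha(I)/\alpha(I_\mathrm{ref})$;
  $m_\mathrm{mask} < 0$ is wake-promoting (positive masking, typical of
  diurnal animals), $m_\mathrm{mask} > 0$ sleep-promoting (negative
  masking).

Arousal state is scored from the MA firing rate: the model is awake when
$Q_m$ strictly exceeds `wake_threshold` (1 s$^{-1}$ by default; ties score
as sleep for determinism), and windowed averages of $Q_m$ (10-min windows
by default) serve as the proxy for activity counts.

## Design choices in detail

**Pacemaker output and relay lag.** The relay sees
$x_\mathrm{lag}$, the $(x, x_c)$ pair rotated by `relay_phase_h` hours —
on the near-harmonic limit cycle this equals $x$ delayed by that lag. The
default is 0. The degu preset uses 4 h: the SPZ–DMH pathway is
multisynaptic, and without a transmission lag the model's consolidated wake
block sits several hours ahead of the light phase for a fast (23-h) clock,
because delay-type entrainment places the pacemaker peak near midday while
the switch anticipates it. The lag is a fitted, physiologically motivated
phase parameter, not a change to the oscillator.

**Masking input is ungated.** The masking pathway reads ambient rather than
eyelid-gated light, and uses the static compressive nonlinearity
$\alpha(I)/\alpha(I_\mathrm{ref})$ rather than the dynamic photoreceptor
signal. Gating masking through the scored wake flag makes a drive jump
discontinuously at every state transition; when the jump approaches the
width of the switch's bistable window (about 1 mV), the hysteresis
collapses and the wake flag chatters at the threshold — an artifact that
can even invert the apparent sign of masking. With ambient-light masking
the drive is a smooth, light-conditional offset and the negative/positive
masking phenomenology is clean. The linear alternative
($f = I/I_\mathrm{ref}$, `masking_mode = "lux"`) is available in the
configuration.

**Noise enters the voltages only**, as `noise_sd * sqrt(dt) * z` per Euler
step with independent standard-normal draws for $V_v$ and $V_m$ from R's
seeded RNG; H, the pacemaker, and $n$ are deterministic. Besides realistic
bout-to-bout variability, noise has one quantitative consequence we rely
on: near the folds the drift of the slow variable is small, so noise causes
early escape, and the expected escape advance grows with the homeostatic
time constant. This makes the ultradian sleep/wake period of the
SCN-lesioned model sublinear in `chi_h` (about 4.3/5.2/6.0 h at
$\chi \times 0.75/1/1.25$ rather than the deterministic proportional
3.9/5.2/6.5 h), matching the reported sensitivity. `noise_sd` is therefore
a fitted parameter of each preset (0.19 mV s$^{-1/2}$ for the squirrel
monkey, 0.05 for the small rodents with their much faster homeostat).

**Initial conditions.** Simulations start asleep at midnight with the
pacemaker seeded near its typical entrained phase: circadian minimum at
22 h clock time for fast clocks (`tau_c_h` < 24, which entrain by daily
delays and place their maximum near midday) and at 5 h for slow clocks
(daily advances, maximum in the late afternoon). Behavior-gated light makes
entrainment basins sticky — an antiphase start can lock a diurnal
parameterization into a self-consistent nocturnal pattern — so the seed
matters and burn-in (default 14 days, discarded) is run under the
protocol's day-1 configuration.

**Integration.** Fixed-step Euler–Maruyama with `dt = 1` s resolves the
fastest time constants (10-s voltages) with ten steps each; halving `dt`
moves the noise-free total sleep fraction by well under half a percentage
point (tested). The wake flag used for light gating and the non-photic
drive is the instantaneous threshold state recomputed after each voltage
update. The stepping core is compiled (Rcpp) and draws its noise from R's
RNG, so `set.seed`/`seed` gives bit-identical trajectories; R
implementations of every right-hand side are exported and tested against
the compiled core step by step.

## Species presets

Presets live as YAML files under `inst/extdata/presets/` with one
provenance tag per value: `lineage` (inherited from the antecedent
sleep-switch/pacemaker model family), `fitted` (constrained here against
the behavioral targets below), `convention` (definitional).

| preset | chi_h | tau_c_h | key relay/masking values | fitted to |
|---|---|---|---|---|
| `human_nominal` | 45 | 24.2 | g=8, c=1.5, m=−0.5 | ~7.5-h consolidated nightly sleep |
| `rodent_generic` | 5 | 24.2 | g=5, c=1.6, m=0 | polyphasic bouts; clear nocturnal↔diurnal range over ν |
| `degu` | 5 | 23.0 | g=6.5, c=1.3, m=−1.5, lag 4 h, G=66600 | LD 30-lux entrainment; diurnal baseline; wheel-inversion switching |
| `squirrel_monkey` | 34.5 | 25.2 | g=18, c=0.24, m=−0.5, G=450 | 36% sleep, monophasic, 25.0-h free-run in LL; lesion behavior emerges |
| `primate_generic` | 20 | 23.8 | g=5, c=1.2, g_lha=±2, ecf=0.2, G=6000 | stable diurnal entrainment in both relay modes |

Fitting followed the same logic as the original study: only the offset of
the circadian signal, the circadian period, the photic sensitivity, and
the homeostatic time constant were adjusted per species; the lesion
experiment then varies a single parameter (`scn_gain` 1 → 0), and the degu
wheel response varies only the signs of `nu_spz` and/or `m_mask`.

Two primate choices deserve a note. The generic primate's
`eye_closure_factor = 0.2` models partial light transmission through closed
lids; with complete gating, the cooperative relay mode naps through the
afternoon, stops sampling the delay-zone light it needs, and loses
entrainment. Its `tau_c_h = 23.8` makes entrainment delay-type so the
circadian peak sits near midday, which is the self-consistent diurnal
configuration under behavior-gated light. Cooperative and competitive modes
differ in total wake (about 30% vs 73%): a stronger MA drive raises $Q_m$,
hence $\mu Q_m$, hence sleep pressure per waking hour — an intrinsic
consequence of firing-rate-proportional H production.

## What the experiments show

```{r sweep, eval = FALSE}
sweep <- run_nu_sweep(seed = 1)
sweep$metrics$diurnality_index
```

* **`run_nu_sweep()`** (rodent, LD 12:12 at 100 lux, masking and DMH/LHA
  relay off): the diurnality index — (wake% in light − wake% in dark)/100,
  an index we define for testability since the phenotypes are described
  verbally in the literature — rises monotonically from about −0.28 at
  $\nu = -1$ to +0.28 at $\nu = +1$, with total wake varying along the
  sweep because the circadian signal does not promote wake and sleep
  symmetrically.
* **`run_relay_modes()`** (primate, LD 500 lux 6–18 h, masking off):
  cooperative relays give a unimodal averaged activity waveform; switching
  only the sign of `g_dmh_lha` makes it bimodal, with a dip in the middle
  of the light period produced by high morning sleep pressure meeting the
  anti-phase LHA drive. Modality is counted on the 24-h folded, 30-min
  smoothed waveform: plateau-safe strict local maxima, peaks closer than
  2 h merged, prominence below 10% of the waveform range ignored.
* **`run_degu_switch()`** (108-day wheel protocol, LD 30 lux 8–20 h then
  DD): inverting both the circadian modulation and masking reproduces
  distinct diurnal→nocturnal switches in LD and DD; circadian-only
  inversion switches but less distinctly in LD; masking-only inversion
  fails in DD. DD diurnality is reported over the first three DD days
  ("onset") as well as the whole epoch, because the 23-h free-run drifts
  about 1 h/day and whole-epoch averages against the projected light phase
  decorrelate toward zero under every hypothesis.
* **`run_scn_lesion()`** (squirrel monkey, LL 500 lux): intact, sleep is
  monophasic (~one long bout per day), totals about 38%, and free-runs at
  about 25.2 h (estimated from the least-squares drift of main sleep
  onsets); lesioned (`scn_gain = 0`, the only changed parameter), sleep is
  polyphasic, totals about 60%, the circadian-binned wake profile
  flattens, and the amplitude spectrum of $Q_m$ shows an ultradian peak
  near 5.2 h that moves to about 4.3/6.0 h when `chi_h` is scaled by
  0.75/1.25 — the homeostat is the generator of the ultradian cycle.

Simulation lengths default to 60 days after burn-in for the sweep, relay,
and lesion experiments (30 for the sweep's wake-percentage averages) and
108 days for the degu protocol; spectra use mean-removed, Hann-windowed
discrete-Fourier amplitudes mapped to period and area-normalized to 1 over
the analysis band.

## What the synthetic conditions do and do not capture

All inputs are idealized square light schedules and instantaneous parameter
switches; there is no twilight, no seasonal photoperiod change, no food
entrainment, thermoregulation, or REM/NREM substructure, and one voltage
noise source stands in for all physiological variability. Activity is a
monotone readout of MA firing, so behaviors with dissociated activity and
arousal (e.g. crepuscular bursts at lights-on/off, which the real degu
data show and these simulations do not) are outside the model's reach.
Passing the packaged checks therefore demonstrates internal consistency
with the modeled mechanisms under laboratory-like protocols, not a fit to
any particular animal recording.

## Degenerate inputs and numerical edges

Schedules must tile 24 h exactly; epochs may not overlap and restore the
base configuration when they end. The photoreceptor fraction is clamped to
$[0,1]$ after each Euler step (the drift alone cannot leave the interval at
the default `dt`). Non-finite states abort the integration naming the step
and variable. Spectra trim the series to a 5-smooth length so the FFT stays
$O(n \log n)$; bout scoring uses strict exceedance so a series exactly at
threshold scores asleep; `free_running_period()` needs at least three main
onsets and warns (or falls back to the spectral fundamental when given the
raw series) on polyphasic records.
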