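---
title: "An ATP-gated model of endothelial cell length dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An ATP-gated model of endothelial cell length dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## Scope

Endothelial cells confined to adhesive line patterns adopt one of three
migration phenotypes, distinguished by their length-versus-time profiles:
*running* cells (REC) hold a roughly constant moderate length, *undecided*
cells (UEC) hold a constant large length, and *tumbling* cells (TEC)
periodically collapse to a rounded state and re-elongate. This package
implements a mechanistic model in which intracellular ATP gates F-actin
turnover, F-actin sets contractility, contractility sets cell length, and
cell length (membrane stretch) feeds back on ATP through stretch-induced
release. The model, its calibration against per-phenotype length
statistics, and a sensitivity analysis over the discriminating parameters
are all exposed through plain R functions with S3 classes.

## Model

Three coupled equations in time \(t\) (seconds), with F-actin concentration
\(a\) (mM), cell length \(L\) (µm) and intracellular ATP \(c\) (mM):

1. **F-actin**: \(\dot a = k (a_h - a) - a\,K(c)\). Regulation pulls \(a\)
   toward the homeostatic level \(a_h\); the ATP-dependent switch rate
   \(K(c) = (k_1 - k_2)\exp\!\big(-c / (M_2 (c_h - c))\big) + k_2\) (for
   \(c < c_h\), else \(k_2\)) eliminates it. \(K\) interpolates from the
   fast rate \(k_1\) at depleted ATP (driving \(a\) to its minimum
   \(a_{\min} = k a_h/(k + k_1)\)) to the slow rate \(k_2\) at homeostatic
   ATP (letting \(a\) reach \(a_{\max} = k a_h/(k + k_2)\)). The slope
   modulator \(M_2\) controls how switch-like the transition is.
2. **Length**: \(\varphi\,\mathrm{d}L = (v_p - \sigma(a) L)\,\mathrm{d}t +
   \varphi\,\beta\,\mathrm{d}W\). Protrusion at rate \(v_p\) opposes
   contractile shortening \(\sigma(a) L\) with contractility
   \(\sigma(a) = \psi a^2 e^{-a/a_{sat}}\) (maximal at \(a = 2 a_{sat}\)).
   For frozen \(a\) this is an Ornstein–Uhlenbeck process with reversion
   rate \(\alpha = \sigma(a)/\varphi\) and mean \(\mu = v_p/\sigma(a)\) —
   the analytic oracle used to test the stochastic integrator
   (`ou_moments()`).
3. **ATP**: \(\dot c = \lambda (c_h - c) - S_{\max} R(L) H(c)\). Production
   relaxes \(c\) to its homeostatic level; stretch-induced release removes
   it at a fraction \(R(L) = \mathrm{clamp}\big(1 - e^{-M_1 (L/L_{\min} -
   1)}, 0, 1\big)^3\) of the maximal rate \(S_{\max}\), gated by a
   two-branch hysteresis relay \(H(c)\) (rising branch \(f_1\): closed
   below \(c_{eq}\), open at \(c_h\); falling branch \(f_2\): open down to
   \(c_{eq}\), closed at \(c_L\); \(f_2 \ge f_1\) everywhere).

The hysteresis loop is what produces tumbling: while ATP recharges
(rising branch) the gate stays closed until \(c\) passes \(c_{eq}\), the
cell elongates, stretch builds up; once release outweighs production the
system crosses to the falling branch, ATP drains along the open gate,
F-actin switches to its fast-elimination regime, contractility spikes and
the cell collapses; at the bottom the gate shuts, and the cycle restarts.

## Parameters and units

Units are fixed globally: seconds, micrometres, millimolar. Baseline
constants shared by all phenotypes (`ec_constants()`): \(k = 347\) s⁻¹,
\(a_h = 0.2\) mM, \(a_{\min} = 0.05\) mM, \(c_L = 1\) mM, \(c_h = 10\) mM,
\(v_p = 25\) µm/s, \(\varphi = 3\times10^{-2}\).

Per-phenotype length statistics (`ec_phenotype_stats()`) drive the
constraint-based derivation (`derive_parameters()`):

* \(k_1 = k (a_h - a_{\min})/a_{\min} = 1041\) s⁻¹;
* \(a_{sat} = a_{\min}/2\), so contractility peaks exactly at the rounded
  state;
* \(\psi = v_p / (L_{\min}\, a_{\min}^2 e^{-2})\), pinning the equilibrium
  length at \(a_{\min}\) to the measured minimum length;
* \(a_{\max}\) as the root of \(\sigma(a) = v_p/L_{ref}\) on the
  decreasing branch (bisection to \(10^{-12}\) mM), with \(L_{ref}\) the
  maximum length for TECs and the mean length for RECs/UECs, and from it
  \(k_2 = k (a_h - a_{\max})/a_{\max}\);
* \(S_{\max} = \lambda (c_h - c_L)/R(L_{\max})\) from the full-stretch
  release balance.

The shape parameters \(M_1, M_2, M_3, c_{eq}\) and the production rate
\(\lambda\) are not fixed by length statistics; they default to the
swarm-optimized per-phenotype values (`ec_optimized_values()`) and are the
free parameters of the calibrator.

One bundled inconsistency is documented in `ec_published_values()`: the
literature UEC contractility constant \(\psi = 752\) mM⁻²s⁻¹ does not
satisfy the minimum-length constraint that defines \(\psi\) (with
\(L_{\min} = 101.9\) µm it gives ≈ 725). The derivation uses the
recomputed value, which is the one consistent with the published UEC
\(k_2 = 351.8\) s⁻¹ (reproduced to < 1%).

## Numerical scheme and the relay trip rule

The integrator (`imex_step()` in R, the same scheme compiled for the
production loop) is an IMEX discretization: the linear relaxation terms are
implicit, the switching functions \(K(c)\) and \(H(c)\) explicit,
Euler–Maruyama for the noise:

* \(a' = (a + \Delta t\, k a_h) / (1 + \Delta t (k + K(c)))\)
* \(L' = (L + \Delta t\, v_p/\varphi + \beta \Delta W) / (1 + \Delta t\,
  \sigma(a')/\varphi)\)
* \(c' = (c + \Delta t (\lambda c_h - S_{\max} R(L') H(c))) /
  (1 + \Delta t\, \lambda)\)

This keeps every update a positive-denominator convex combination, so the
deterministic system is unconditionally bounded: \(c \in [c_L, c_h]\),
\(a \in [a_{\min}, a_{\max}]\) (both verified as test properties).

**Relay trip rule.** A subtle design point is *when* the hysteresis
switches branch. Tripping on the sign of the discrete ATP increment
\(c^{n+1} - c^n\) fails in practice: on the rising branch the drive
\(\lambda(c_h - c) - S_{\max} R\, f_1(c)\) has a *stable* zero just below
\(c_h\) (for the TEC parameters at \(\varepsilon^\ast = c_h - c \approx
4.6\times10^{-3}\) mM), so the increment approaches zero from above without
ever changing sign and the system stalls permanently at full elongation
instead of cycling. Tripping at exact equality is no better: whether the
increment ever evaluates to exactly zero depends on floating-point
round-off and on \(\Delta t\). The package therefore trips the relay on
the *drive* itself with a small tolerance: rising → falling when the drive
falls to \(\le \tau\), falling → rising when it recovers to \(\ge -\tau\),
with \(\tau = 10^{-12}\) mM/s (`tol_drive`). The tolerance is a rate, so
the rule is step-size independent; episode onset times at
\(\Delta t = 10^{-2}\) and \(10^{-3}\) s agree to better than a minute
over 12 h.

A consequence worth knowing: with this rule the REC/UEC ATP variable also
cycles (between ≈ 8.0 and ≈ 9.98 mM) rather than resting at the stalled
balance point. Their *length* is unaffected — over that ATP range the
switch rate stays at \(k_2\) (the REC/UEC \(M_2 = 0.016\) makes \(K\)
essentially flat there), so F-actin and length remain at their fixed
point, which is what the phenotype requires.

**Step sizes.** The reference step is \(\Delta t = 10^{-3}\) s; production
sweeps and calibration use \(10^{-2}\) s, validated against the reference
by a convergence property (relative length difference \(< 0.5\%\) on
non-switching runs; tumbling onset times within 1 min). A 12-h
deterministic run at \(\Delta t = 10^{-2}\) s takes well under a second of
wall time.

## Statistical cell and the synthetic-trace generator

Calibration does not fit raw single-cell data but a *prototype*
("statistical cell") profile per phenotype (`make_prototype()`): a
constant series at the mean length for RECs/UECs, and for TECs a square
wave starting in the rounded state — low at \(L_{\min}\) for \(T_P\)
seconds, high at \(L_{\max}\) for \(T_I\) seconds.

`synth_trace()` generates experiment-like traces (default 2-min frames
over 24 h) for testing the measurement and classification pipeline:

* REC/UEC: an exact-transition OU path around the mean length. The
  reversion rate is chosen so the stationary standard deviation is one
  third of the distance from the mean to the nearer length bound (keeping
  essentially the whole path inside the observed range before clipping).
* TEC: a square wave whose dwell times are drawn uniformly around the mean
  durations, with the jitter half-width capped so draws stay inside the
  observed 10-min–4-h episode range; OU noise (3 µm stationary sd) is
  superimposed on the elongated level only, since rounded cells show
  little length fluctuation.

`measure_trace()` inverts the generator: extrema, mean, the
quadratic-variation noise estimate \(\hat\beta = \mathrm{sd}(\Delta L) /
\sqrt{\Delta t_{frame}}\) (consistent only when the frame is short against
the reversion time — at 2-min frames it is biased low by design; the test
suite estimates at 1-s frames), and tumbling episode statistics with
episodes defined as runs of frames below 20 µm.

## Calibration

`ec_calibrate()` fits the free shape parameters by global-best particle
swarm optimization (`pso_minimize()`: 40 particles, 200 iterations,
inertia 0.72, cognitive = social = 1.49, positions clipped to bounds,
reproducible from a seed). Rates and shape coefficients spanning decades
(\(M_1, M_3, \lambda\)) are searched in log₁₀ space. The reference
objective is the discrete \(L^2\) mismatch between the deterministic
simulation and the prototype profile; a `"features"` objective (relative
mismatch of oscillation extrema and timing) is available for periodic
targets, where phase drift makes the \(L^2\) landscape rugged. For TECs
the free set is \(M_1, M_2, \lambda, c_{eq}\) with \(M_3\) pinned in the
sharp-relay regime (\(10^{-5}\)); for RECs/UECs it is \(M_1, M_2, M_3,
c_{eq}\) with \(\lambda\) fixed. Simulation failures inside the swarm
return a large finite penalty rather than an exception.

## Sensitivity analysis

`sweep_parameter()` (one-at-a-time) and `phase_diagram()` (over
\(c_{eq} \times M_2 \times M_3\)) classify each run as `tumbling`,
`constant`, or `constant_with_transient` (`classify_regime()`, 2-h
transient discard, 20-µm tumbling threshold). Reproduced qualitative
trends: oscillation frequency increases with \(\lambda\) and with
\(c_{eq}\); tumbling-phase duration increases with \(M_2\); the crest ATP
level decreases with \(M_3\); tumbling occurs for intermediate
\(c_{eq}\) combined with switch-like \(M_2\) and sharp \(M_3\), and is
absent at the REC/UEC parameter corner. `c_steady` is reported as the
post-discard ATP maximum — the production/release balance level at the
crest of the charge cycle — which is well-defined in both cycling and
constant regimes.

## Problem sizes and limitations

* A 12-h deterministic run at \(\Delta t = 10^{-2}\) s is \(4.3\times10^6\)
  steps (< 1 s); at \(10^{-3}\) s, ~3 s. A full 40×200 PSO calibration is
  ~8000 simulations (tens of minutes); tests use reduced budgets.
* The model reproduces *prototype* profiles, not cell-to-cell
  variability; the noise amplitude \(\beta\) is fitted separately from the
  deterministic skeleton.
* Timing of the tumbling cycle is sensitive to the release-onset detail
  near \(c_h\); simulated \(T_P\)/\(T_I\) agree with the measured means to
  within ~5–8%, inside the scheme-sensitivity tolerance.
* The relay trip rule is a modelling choice (see above); alternatives that
  trip strictly on discrete-increment sign changes stall and cannot
  produce sustained oscillation under this discretization.
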