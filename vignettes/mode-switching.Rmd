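---
title: "Modelling mode switching of the mitochondrial Na+-Ca2+ exchanger"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling mode switching of the mitochondrial Na+-Ca2+ exchanger}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitoncx)
```

## The physical picture

A depolarised mitochondrion has essentially no uniporter current, so its
only inner-membrane Ca²⁺ pathway is the electrogenic Na⁺–Ca²⁺ exchanger
(n Na⁺ per Ca²⁺, n ≥ 3). The exchanger's direction is set by a single
thermodynamic quantity, the free energy of one forward cycle
(n Na⁺ cytosol→matrix, 1 Ca²⁺ matrix→cytosol):

$$\Delta G = nRT\,\ln\frac{[\mathrm{Na}]_m}{[\mathrm{Na}]_c}
  + RT\,\ln\frac{[\mathrm{Ca}]_c}{[\mathrm{Ca}]_m} + (n-2)F V_m.$$

Setting $\Delta G = 0$ gives the matrix Ca²⁺ the exchanger drives
toward, the *reversal point*:

$$[\mathrm{Ca}]_m^* = [\mathrm{Ca}]_c
  \left(\frac{[\mathrm{Na}]_m}{[\mathrm{Na}]_c}\right)^{n}
  e^{(n-2)FV_m/RT}.$$

Under the standard depolarised conditions (Na⁺ 4.54/10 mM, −20 mV,
298 K) the resting reversal point is ≈ 4.3 nM, and a 15 μM cytosolic
spike moves it to ≈ 0.64 μM. An oscillating cytosolic drive therefore
drags the matrix alternately toward two very different set points — the
exchanger runs in reverse (import) during each spike and forward
(export) between spikes, and the matrix free Ca²⁺ oscillates in step
with the cytosol. That relaxation-toward-a-moving-set-point dynamic is
the entire mechanism; everything else in the package is bookkeeping
around it.

```{r example}
drive <- generate_oscillating_drive(oscillation_spec(
  peak = 1.5e-5, period = 60, spike_width = 20, n_spikes = 10,
  duration = 600, desens_decay = 0, shape = "square"))
traj <- simulate_matrix(drive, membrane_state(), exchanger_params(),
                        simulation_params())
summarize_oscillations(traj$time_s, traj$ca_free_M, trajectory = traj)
```

## The flux law and why it has this form

The single-exchanger kinetics are not fully constrained by the data the
model is meant to reproduce: only the *sign* of the flux, its switching
point and its saturation scale matter for mode-switching behaviour. We
therefore use a reduced carrier law chosen to be exactly thermodynamically
consistent rather than a fitted multi-state cycle:

* **Numerator** $[\mathrm{Na}]_c^n[\mathrm{Ca}]_m e^{-\theta} -
  [\mathrm{Na}]_m^n[\mathrm{Ca}]_c e^{+\theta}$ with
  $\theta = (n-2)FV_m/2RT$ — mass action for the two cycle directions
  with the translocated charge split symmetrically across an Eyring
  barrier. The symmetric split is the conventional neutral choice; the
  reversal point is independent of how the exponent is split.
* **Denominator** $(K_{Na}^n+[\mathrm{Na}]_c^n)(K_{Ca}+[\mathrm{Ca}]_m)
  e^{-\theta} + (K_{Na}^n+[\mathrm{Na}]_m^n)(K_{Ca}+[\mathrm{Ca}]_c)
  e^{+\theta}$. Each product dominates the corresponding numerator term,
  so $|f| \le k_t$ for *every* admissible state, including strong
  polarisation where $e^{|\theta|}$ is large ($\approx 33$ at −180 mV).
  A voltage-independent saturating denominator would violate that bound
  there, which is why the Eyring factors appear on both levels. The
  denominator is strictly positive, so the flux's zero coincides exactly
  with $\Delta G = 0$ — the property the whole analysis leans on — and
  the flux is strictly monotone in each concentration and in voltage
  (for n > 2).

The flux law is a small pluggable function; a full multi-state cycle
model with measured rate constants could be substituted without touching
the simulator, as long as it keeps the same reversal point.

## Parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| n (Na⁺:Ca²⁺) | 3 | — | most-cited electrogenic stoichiometry; configurable because the true value is debated |
| k_turnover | 2030 | ions/s | calibrated, see below |
| K_Ca | 10 μM | M | literature-scale Ca²⁺ affinity; results are sign/shape-driven, not affinity-sensitive |
| K_Na | 8 mM | M | literature-scale Na⁺ affinity |
| V_m | −20 mV | V | depolarised (FCCP-like) regime; −180 mV for energised scenarios |
| T | 298 K | K | room-temperature imaging |
| [Na⁺]_m / [Na⁺]_c | 4.54 / 10 | mM | fixed — Na⁺ pools are orders of magnitude above the transported Ca²⁺, so their depletion is negligible |
| V_mito | 1.31e−15 | l | capped cylinder, length 1 μm, radius 0.5 μm |
| buffering factor | 100 | — | total/free matrix Ca²⁺; 1000 as the high-buffering variant |
| N_NCX | 100 | — | mitoplast patch-clamp channel counts suggest O(100–500) transporters; swept 1–10,000 |

**k_turnover calibration.** No per-transporter turnover number is
available for this exchanger, so the scale is fixed by a functional
requirement: with 100 exchangers and buffering 100, a 20-s, 15 μM
square spike must carry the matrix across ≥ 90% of the gap between the
two reversal points — i.e. 100 transporters suffice for essentially
full-amplitude oscillations. `calibrate_turnover()` solves this by
root-finding; it returns 2029.9 ions/s under the default geometry and
the default was frozen at 2030. The resulting single-transporter rate
(~2000 ions/s at saturation) is physically reasonable for a carrier.

**The activation gate.** Reverse-mode activity empirically needs a
small pre-existing rise in matrix Ca²⁺ (supplied by residual uniporter
leak or by low-dose ionomycin). The optional gate multiplies the flux
by a Hill term $[\mathrm{Ca}]_m^h/([\mathrm{Ca}]_m^h + K_{act}^h)$ with
K_act = 50 nM. We set h = 4 rather than a shallower cooperativity: with
h = 2 the gate leaks ~0.7% of full flux at the 4.3 nM resting point,
which is enough for the first cytosolic spike to bootstrap the gate
open and the "unprimed" scenario oscillates anyway. With h = 4 the
unprimed matrix stays within ~0.5 nM of rest over 600 s, while a
preload just above K_act (the `ionomycin_trigger` preset uses 80 nM)
restores full oscillations — the gate then genuinely encodes the
trigger-Ca²⁺ requirement as a testable dichotomy.

## Mode labels and the dead band

As the matrix approaches a reversal point the flux decays asymptotically
toward zero without ever changing sign, so a strict-sign classification
would label long equilibrated stretches "reverse" at −180 mV even though
the exchanger moves less than one ion per transporter per several
seconds. Per-sample mode labels therefore use a dead band: |f| ≤ 1
ion·s⁻¹ per exchanger (below one transport cycle per second, i.e. below
the granularity of the transport process itself) is labelled `null`;
`classify_modes()` attaches null samples to the following signed
segment, so segment boundaries still follow the sign structure. The
threshold is configurable (`null_tol`); occupancy comparisons between
−20 mV and −180 mV are insensitive to it across several orders of
magnitude because the −20 mV fluxes are O(10–100) ions/s while the
−180 mV reverse fluxes never exceed ~0.2 ions/s.

## The synthetic drive generator

There is no public drive dataset, so cytosolic inputs are generated.
The generator emulates agonist-evoked, fura-2-like oscillation trains:
100 nM baseline; raised-cosine spikes (width 20 s) to 1.5 μM (measured
bulk) or 15 μM (ER–mitochondria microdomain estimate); one spike per
50 s over 600 s (≈12 spikes, within the observed one-per-40–70 s
cadence); amplitudes declining 5% per spike for receptor
desensitisation; optional Gaussian jitter on spike timing and optional
Gaussian noise added *on the fluorescence-ratio scale* (where camera
noise lives), hence multiplicative on concentration. Square spikes are
available for calibration and worst-case (discontinuous) solver tests,
and a two-level washout step emulates BAPTA perfusion for forward-mode
decay measurements. "Scaled logarithmically" is implemented as
log-linear interpolation anchored so the ratio extrema map exactly to
100 nM and the chosen high concentration — the only logarithmic reading
that anchors both endpoints — and the inverse map is provided for
round-trip tests.

What the generator does *not* emulate: the mechanistic cytosolic
oscillator (InsP₃ receptor dynamics, store-operated entry),
cell-to-cell variability in spike shape, photobleaching, or movement
artefacts. Passing tests therefore demonstrate that the transport model
and metrics behave correctly for drives with the right amplitude,
cadence and noise structure — not that the pipeline is robust to every
pathology of real recordings.

## Numerical choices

* **Integrator**: `deSolve::ode` (lsoda), stiff-capable and adaptive —
  the problem stiffens with exchanger count; at N_NCX = 10,000 the
  matrix relaxes in well under a second of model time.
* **Tolerances**: rel 1e−10, abs 1e−14 M. Free matrix Ca²⁺ visits
  ~4e−9 M, so the absolute tolerance must sit several orders below
  that; with these defaults trajectories are reproducible to ~1e−6
  relative under tolerance halving and grid doubling (the acceptance
  bound is 1e−3).
* **Drive interpolation**: linear between samples; outputs on the
  drive's grid (default 0.5 s, matching 0.5 Hz acquisition). Sharp
  washout steps integrate cleanly (verified by tolerance-halving
  checks).
* **Initialisation**: steady state at the drive's first sample —
  buffering × the closed-form reversal point — so trajectories start at
  zero flux. A constant drive stays flat to < 0.1% over 600 s.
* **Positivity**: concentrations are validated strictly positive; a
  non-positive excursion aborts with the failure time (it indicates a
  step-size misconfiguration, not a recoverable state).
* **Peak detection**: local maxima (plateau-aware) with prominence
  ≥ 0.2 × the trace's post-onset excursion, amplitude measured above a
  per-peak local baseline (the minimum since the previous accepted
  peak), which is robust to slow drift. The threshold is configurable
  and recorded in the output metadata; no universally agreed minimum
  amplitude exists for calling an oscillation, so the default is a
  stated convention, not a fitted value.
* **Binning**: half-open `[onset + k·200, onset + (k+1)·200)` bins —
  boundary peaks go to the later bin; out-of-window peaks are counted
  and reported, never silently dropped.
* **Half-times**: linear interpolation between samples, measured from
  the washout event marker; a trace that never reaches half level
  returns a flagged `NA` rather than an error, since "does not decay"
  is a scientifically meaningful outcome (forward mode unavailable).

## Problem sizes

The shipped tests and the acceptance script use 600-s drives sampled at
0.5 s (1201 samples), 10–12 spikes, exchanger sweeps over 1–10,000, and
1000-draw random-state ensembles for the thermodynamic property checks;
each simulation completes in well under a second, a full preset run in
a few seconds.

## Known limitations

* Single well-mixed compartment; no intra-matrix gradients, no
  mitochondrial population heterogeneity.
* The membrane potential is a constant per run; depolarisation
  transients (e.g. during FCCP application) are not modelled.
* No MCU, permeability-transition-pore, Letm1 or pH fluxes; the
  exchanger is deliberately the only Ca²⁺ pathway.
* No feedback from matrix Ca²⁺ onto the cytosolic drive — the drive is
  prescribed, mirroring the experimental design where cytosolic Ca²⁺ is
  measured, not modelled.
* The flux law is a reduced carrier model: faithful in reversal point,
  sign structure, monotonicity and saturation, but not a fit to
  measured exchanger kinetics; absolute fluxes inherit the calibration
  convention for k_turnover.
* Li⁺-for-Na⁺ substitution is an extension point (the monovalent ion
  enters only through its concentrations and stoichiometry), not an
  implemented kinetic scheme.
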