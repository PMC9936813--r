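---
title: "Model, analyses and filter design in olmcell"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model, analyses and filter design in olmcell}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its science: the reduced OLM
interneuron model and its assumptions, the in-vivo-like (IVL) machinery, the
resonance and spike-triggered-average (STA) statistics, and the robust
adaptive unscented Kalman filter (RAUKF). It also records the design choices
made where the design was genuinely open, and what the tests do and do not
establish.

## The reduced model

The cell is one isopotential compartment:

$$C\frac{dV}{dt} = I_{stim}
 - \bar g_{Na} m^3 h\,(V - E_{Na})
 - \bar g_{Kdrf} n^4\,(V - E_K)
 - \bar g_{Ka} a^3 b\,(V - E_K)
 - \bar g_{M} z\,(V - E_K)
 - \bar g_{h} r\,(V - E_h)
 - g_L (V - E_L)$$

with first-order gates $\dot x = (x_\infty(V) - x)/\tau_x(V)$,
$x_\infty(V) = 1/(1 + e^{(v_h - V)/k})$ and bell-shaped
$\tau_x(V) = \tau_b + \tau_a / (e^{(V-v_1)/k_1} + e^{-(V-v_2)/k_2})$.
Units package-wide: mV, ms, pA, µS, pF; channel maximal conductances are
stored as densities (S/cm²) times a compartment area, the convention in
which the reference values gM = 1.91e−5, gKdrf = 4.33e−3, gKa = 7.31e−3 and
gNa = 4.85e−3 S/cm² are meaningful. (Read as *total* conductances these
numbers cannot sustain an action potential against an OLM-scale capacitance;
as densities they are entirely typical.)

**Kinetics are data, not code.** The exact gating equations of the
antecedent OLM models are not part of this package's sources, so
`inst/extdata/reference_model.json` carries *provisional* kinetics written
in the style of that model family: transient Na (m³h), fast
delayed-rectifier K (n⁴), A-type K with inactivation (a³b), a
non-inactivating slow M-type K, and a slow hyperpolarization-activated
h-current. Any of it can be replaced by editing the JSON; all analyses are
agnostic to the specific gate set.

**Calibration of the provisional parameters.** The free passive/kinetic
parameters were pinned *once*, by construction rather than fitting, to the
operating points that define the modelled cell:

* rest at −70 mV with zero input (leak reversal solved analytically);
* ≈1 Hz firing at ≈24 pA injected current (the published operating point is
  25.5 pA; this quantity is kinetics-sensitive, which is why it is treated
  as a calibration with a generous band);
* under the representative OU background of set 0, subthreshold mean
  ≈ −69 mV, subthreshold sd ≈ 2.6 mV, ISI CV ≈ 0.8 and 3–5 Hz firing —
  i.e. inside the comparability bounds the IVL search itself imposes
  (−70 < mean < −67.5 mV, 8 < variance < 10 mV²; the realized variance sits
  slightly below this window, a known residual of the calibration);
* no stable depolarized equilibrium: the delayed rectifier is deliberately
  slow (τ ≈ 5–8 ms near −55 mV) and low-threshold, so the depolarized fixed
  point of the fast subsystem is unstable and the cell fires tonically
  instead of latching into depolarization block. This is the classical
  relaxation-oscillator escape and it is the load-bearing choice: fast
  rectifier variants of the same steady-state curves latch at ≈ −45 mV.

Two kinetic slopes (Na activation k = 2.2 mV, its inactivation k = −3.3 mV)
are steeper than single-channel Boltzmanns usually are; they encode in two
parameters what the antecedent models achieve with rate-function asymmetry,
and they are the main reason the model both fires from ≈ −63 mV and escapes
block. They are provisional in the same sense as everything else in the
JSON.

**Integration.** Exponential Euler for gates, forward Euler for V, default
dt = 0.025 ms. The discrete charge balance
$C\,\Delta V/\Delta t + \sum I - I_{stim} = 0$ holds to rounding at every
sample and is asserted in the tests. Halving dt moves subthreshold voltage
by < 0.1 mV and early spike times by a few ms (threshold crossings are the
dt-sensitive part); the property tests encode exactly that.

## Stimuli and the OU background

Synaptic drive follows the point-conductance formulation
$I_{syn} = g_e(t)(V - E_e) + g_i(t)(V - E_i)$ with OU conductances
$dg/dt = -(g - g_0)/\tau + D\,N(t)$, integrated by the *exact* discrete
transition (no time-step bias; stationary mean $g_0$, variance
$D^2\tau/2$). Negative excursions are kept in the series and clipped to
zero only where the conductance meets the membrane.

Defaults: $\tau_e$ = 3 ms, $\tau_i$ = 10 ms, $E_e$ = 0 mV and
$E_i$ = −87 mV. The inhibitory reversal deserves a note: with the
representative mean conductances (ge0 ≈ 0.0032, gi0 ≈ 0.0109 µS) the
synaptic balance point $(g_{e0}E_e + g_{i0}E_i)/(g_{e0}+g_{i0})$ must fall
near the −70…−67.5 mV window for the IVL statistics to be attainable at
all; $E_i$ = −75 mV would put it at ≈ −58 mV regardless of the intrinsic
conductances, while −87 mV (a common choice in hippocampal interneuron
modelling) puts it at ≈ −67 mV. This is a structural requirement, not a
tuning knob.

Perturbations are double-exponential conductance events, peak-normalized to
30× a single synaptic weight (0.006 µS excitatory, 0.0054 µS inhibitory),
repeated at the perturbation frequency; event kinetics (rise/decay 0.5/3 ms
exc., 1/8 ms inh.) are configurable defaults.

## IVL states, resonance, PRC, STA

A 10-s trace is IVL-valid when all four strict criteria hold: subthreshold
mean > −70.588 mV and sd > 2.2 mV (computed after deleting ±7 ms around
every spike peak, overlapping windows merged), ISI CV > 0.8, and rate
(spike count / 10 s) strictly between 3 and 25 Hz. The constrained search
evaluates every grid point once and additionally requires
−70 < mean < −67.5 mV and 8 < variance < 10 mV². Representative sets are
chosen by greedy farthest-point sampling in the (min f, max f) plane over
50 shared seeds — a deterministic reading of "span the firing-rate space".

Spiking resonance: spike onsets (upward crossings of −10 mV, 1-ms
refractory floor) are binned at 1 ms and Welch spectra taken with one
10,000-sample segment, so the 0.1-Hz grid resolves the 1-Hz-spaced
perturbation set. (Windowing the raw dt grid with the conventional 20,000
sample segment would give 2-Hz resolution and could not separate adjacent
perturbation frequencies; binning is the deliberate deviation.) The
baseline ratio δPSD is evaluated at the grid bin nearest $f_i$, baseline
and perturbed runs share the OU seed, ties in the argmax resolve to the
lowest frequency, and a zero baseline density marks the frequency
undefined.

PRC: the reference cycle is the first whose preceding ten ISIs have
CV < 1% (skipping the slow-adaptation transient), perturbations are placed
at 20 uniform phases, and the phase shift is reported as
$\Delta\phi = (T_0 - T_1)/T_0 \times 100$ so that *positive means advance*
— the printed formula convention and the verbal convention in the source
literature disagree, and the verbal meaning is implemented. Per-current
changes compare maximum absolute amplitudes between the 2nd-last
pre-perturbation spike → perturbation window and the perturbation → 2nd
following spike window.

STA: windows span 195–10 ms before spikes preceded by ≥200 ms ISIs; the
recorded quantity is each intrinsic current's signed share of the total
absolute intrinsic current (synaptic inputs excluded). Across-set
normalization maps |means| onto [0, 1] by the min–max over sets *and*
timepoints of each (current, f_r) slice; slopes are OLS fits of the
across-set mean on −195…−25 ms, and spread is twice the across-set
(population-denominator, configurable) standard deviation summed over the
analysis timepoints — the operational Methods-text definition, in
preference to a figure caption that reads like a mean difference.

## The RAUKF

Augmented state $X = [V, \text{gates}, \theta]$,
$\theta = (g_M, g_{Kdrf}, g_{Ka}, g_{Na})$ as densities, propagated by the
model itself (each sigma point integrates one step with its own θ) with θ a
random walk; injected current is a known control. The observation is V at
every sample; since the observation map is linear, the measurement update
is computed exactly from the predicted moments (on a linear-Gaussian system
the whole filter collapses to the closed-form Kalman filter, asserted to
1e−8 in the tests).

Initialization follows the magnitude rule: for each θ component,
$P_{ii} = 10^{2\lfloor\log_{10}\theta_i\rfloor}$ (an uncertainty of one
order of magnitude); voltage/gate blocks start at P = 1e−4 and Q = 1e−8.
The "poor" start is $\theta_0 = 10^{\lfloor\log_{10}\theta\rfloor}$.

Three filter-design points were genuinely open and are resolved as follows:

* **Sigma-point scaling.** α = 0.5 (β = 2, κ = 0). The textbook small-α
  choice (1e−3) concentrates the sigma points so tightly that the one-step
  θ→V cross-covariance vanishes numerically and the conductances are never
  pulled from a poor start; α = 0.5 restores identifiability without
  destabilizing the spike nonlinearity.
* **θ random-walk size.** The baseline is small,
  $Q_\theta = 10^{-6} P_\theta$: large enough for fine tracking, small
  enough that converged estimates do not diffuse. The large early Q needed
  to travel from a poor start is supplied by the adaptation itself (below).
* **Transient robustness.** On a fault — normalized innovation squared
  $\varepsilon = \nu^2/S$ above the χ²(1) 0.95 quantile — the noise models
  update as convex combinations
  $R \leftarrow (1-\delta)R + \delta\,\max(\nu^2 - C_{yy}, \epsilon_0)$,
  $Q \leftarrow (1-\lambda)Q + \lambda (K\nu)(K\nu)^\top$ with
  $\delta = \max(\delta_0, (\varepsilon - b)/\varepsilon)$,
  $\lambda = \max(\lambda_0, (\varepsilon - a)/\varepsilon)$,
  $\lambda_0 = \delta_0 = 0.2$, a = 10 ≫ b = 1. The addition here is that
  both Q and R then *relax back to their baselines* with a 50-ms time
  constant. Without the relaxation a single spike-timing fault permanently
  inflates $Q_{\theta\theta}$ (rank-one outer product) and the estimates
  random-walk by several percent for the rest of the recording; with it,
  the robustness is transient, which is what a fault is.

The synthetic observation adds 0.25 mV Gaussian measurement noise to the
simulated voltage (a clean patch recording; the source protocol does not
state a value) and the filter is told that variance as R₀. Under the full
noisy step train (500 ms lead-in + 4 × the 7-step staircase, 5,988 ms,
239,520 updates, 25 sigma points) both initializations converge to the same
estimates with all four conductances within ~1% of truth, the M-type
conductance — three orders of magnitude smaller than the others — being the
least identifiable, exactly the pattern the estimation problem dictates.

## What the synthetic data do and do not show

Every input here is self-generated: the "experiment" is the model observed
through noise. Passing tests therefore demonstrate internal consistency —
the estimator recovers what generated the data, the resonance statistic
detects entrainment that is really there — not that the provisional
kinetics are the true OLM kinetics. Quantities tied to the kinetics (the
exact rheobase, the IVL rate band, which STA current dominates) carry wide
tolerances or rank-level assertions for that reason. Two qualitative
discrepancies are known and accepted: with these kinetics the M-current's
share of the total current is smaller than the h-current's (the source
model family reports the reverse), and inhibitory perturbations *decrease*
the M-current's maximum amplitude while driving the h-current's up. Both
follow from the small M conductance at subthreshold voltages in the
provisional gate set.

## Problem sizes

The full-scale analyses behind the science (≈16⁴-point IVL grid, 50,000
resonance states, 10⁴–10⁵-seed STA harvests) are cluster-scale by design.
The package runs them at reduced scale as its standard checks: a 5-frequency
× 30-state polarity comparison, a 3-set × 5-frequency STA harvest with a
12-seed budget per set, fifty 10-s realizations for the representative-set
rate check, and the full 6-s estimation train for the filter. These sizes
were chosen as the smallest at which the qualitative claims are stable
across seeds.
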