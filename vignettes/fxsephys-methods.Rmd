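---
title: "Models and methods behind fxsephys"
author: "fxsephys authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind fxsephys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fxsephys)
```

## What the package computes

`fxsephys` implements the analysis chain used to phenotype layer-5
prefrontal pyramidal neurons from patch-clamp recordings, together with a
conductance-based simulator that generates every protocol the analysis
consumes. The two sides are deliberately matched: every feature extractor
can be validated against a model whose ground truth is known in closed
form, and the simulator's genotype-by-class presets let the entire cohort
pipeline — from raw sweeps to a knockout-vs-wild-type direction summary —
run with no experimental data.

The analysis side covers three recording modalities:

* **Subthreshold current clamp** — input resistance from the linear portion
  of the current–voltage relation, voltage sag and rebound from
  hyperpolarizing steps, the functional membrane time constant from
  averaged brief-pulse decays, the impedance amplitude profile (ZAP) and
  resonant frequency from a 1–15 Hz chirp, temporal summation of simulated
  EPSC trains, and the resting potential.
* **Action-potential threshold dynamics** — the 20 mV/ms first-derivative
  threshold criterion, reproducible just-threshold searches by bisection,
  strength–duration (threshold accommodation) curves, and phase-plane
  trajectories.
* **Outside-out voltage clamp** — scaled-trace leak subtraction, the
  three-protocol decomposition of the total K⁺ current into
  fast-inactivating (Kv4-like), slowly inactivating (Kv1-like) and
  sustained components, back-extrapolation of the slow component,
  Boltzmann activation fits, inactivation and two-pulse recovery kinetics,
  h-current step analysis, and drug-sensitive currents by trace
  subtraction.

## The neuron and patch model

Cells are one- or two-compartment conductance-based models. Every channel
carries Hodgkin–Huxley first-order gates with Boltzmann steady states

$$x_\infty(V) = \frac{1}{1 + e^{-(V - V_{1/2})/k}},\qquad
\tau_x(V) = \tau_{\min} + (\tau_{\max}-\tau_{\min})
            e^{-\left((V-V_{\mathrm{peak}})/w\right)^2},$$

with $k > 0$ for activation and $k < 0$ for inactivation; voltage-
independent time constants are the special case
$\tau_{\min}=\tau_{\max}$. A channel current is
$I = \bar g\, m^p \left(\sum_j f_j h_j\right)(V - E)$; the component list
$\{(h_j, f_j)\}$ holds any multi-exponential gate, and is how the
h-current's double-exponential activation is expressed (two kinetic
components, fractions 0.7/0.3, time constants 50 and 300 ms, sharing one
activation curve at $V_{1/2}=-82$ mV, $k=-9$ mV).

Current clamp integrates
$C \dot V = -\sum_i I_i + I_{\mathrm{axial}} + I_{\mathrm{bias}} +
I_{\mathrm{stim}}$ with an exponential-Euler scheme at steps of at most
25 µs; gate steady states and per-step decay factors are tabulated on a
0.2 mV grid, the standard device of compiled neuron simulators. Holding at
−65 mV is enforced by solving the bias current from the algebraic steady
state, so the pre-stimulus baseline is exact rather than settled. Halving
the step changes any reported voltage by well under 0.05 mV (tested).

Voltage clamp assumes a perfect clamp. Because every command is piecewise
constant, each gate relaxes exponentially within a segment and the gating
trajectory is evaluated in closed form — the voltage-clamp side of the
simulator has no integration error at all. Patch currents are the
channel sum scaled by the patch's membrane fraction, low-pass filtered
(4-pole Butterworth, 2 kHz by default) and given additive Gaussian noise,
mirroring excised-patch acquisition (10 kHz sampling, 2 kHz analog
filter). Current-clamp sweeps optionally carry additive voltage noise
(0.2 mV SD in the cohort battery): feature precision should reflect
recording practice, not the femtovolt precision of a noiseless simulation,
and several "no difference between genotypes" checks are only meaningful
when microscopic systematic residues sit below a realistic noise floor.

Reversal potentials default to $E_K=-96$, $E_h=-30$, $E_{Na}=+55$ mV, with
the leak reversal a preset parameter; voltages follow the whole-cell
convention of not correcting the liquid-junction potential, and the
metadata records that flag. Temperature is fixed at 33 °C with no Q10
machinery. There are no cable morphologies, synaptic conductances, or
stochastic single-channel gating.

## Presets and what they are calibrated to

No absolute conductance densities or patch areas are available for these
cells, so the presets are calibrated so that *extracted features of
simulated cohorts* land on the printed whole-cell statistics:

* wild-type PT soma: input resistance 79.5 MΩ, resonant frequency
  ≈ 4.1 Hz, resting potential ≈ −67 mV, and somatic K⁺ component
  fractions ≈ 43% fast / 48% slow of the total peak;
* IT soma: input resistance ≈ 113 MΩ and no resonance (≈ 1 Hz);
* K⁺ kinetics: fast A-type inactivation ≈ 28 ms and slow (Kv1-like)
  inactivation ≈ 620 ms at +50 mV, recovery time constants separated by
  more than an order of magnitude.

Knockout presets then differ **only** by the stated conductance scalings —
PT: h-current ×0.6, fast A-type ×1.35, slow Kv1-like ×0.6; IT: identical
conductances with a −3 mV leak-reversal shift (resting potential only) —
plus the dendritic Kv4 activation midpoint, which is 8 mV hyperpolarized
relative to the soma in wild type and unshifted in knockout. Everything the
knockout phenotype shows downstream (less sag and rebound, lower resonant
frequency, longer time constant, greater summation, the flipped K⁺
fractions, lower just-threshold currents) is *emergent* from those
scalings, not separately dialed in.

The slow K⁺ current's inactivation time constant is bell-shaped in voltage
(≈ 2.5 s near −20 mV, ≈ 730 ms at +50 mV) so that the 100-ms prepulse to
−20 mV inactivates the fast current while sparing the slow one — the
assumption the three-protocol decomposition rests on — while the measured
inactivation at +50 mV stays in the printed range. Somatic K⁺-decomposition
patches exclude the h-channel (its somatic density is negligible in real
excised patches, and a patch dominated by gated h-conductance would defeat
small-step leak scaling); the h-current protocol instead uses a leak+H
patch, and the Na⁺ current is always absent from patches (TTX convention).

Cohorts draw per-channel densities from lognormal distributions centred on
the preset means. The default coefficient of variation (0.08) is a
calibration to the *published post-hoc power* of the significant
comparisons (mostly above 94% at n ≈ 15): the raw printed SEMs imply much
larger cell-to-cell CVs (~0.3), but several derived features of a
single-compartment model carry structurally smaller effect sizes than
their biological counterparts, and matching the study's sensitivity rather
than its raw dispersion keeps the simulated experiment statistically
equivalent to the real one.

## Numerical and definitional choices

* **"Linear portion" of the I–V curve**: the maximal contiguous amplitude
  window spanning 0 pA whose OLS fit has $R^2 \ge 0.99$; spiking sweeps
  are excluded with a warning.
* **Windows**: steady state = last 200 ms of a 1000-ms step; sag peak
  search = first 200 ms; rebound = 400 ms after offset; transient K⁺ peaks
  = 50 ms after the test-step onset; sustained amplitude = mean of the last
  50 ms of the step. The sag ratio averages the three largest
  hyperpolarizing steps.
* **ZAP**: $Z(f) = |\mathrm{FFT}(V - \bar V)| / |\mathrm{FFT}(I - \bar I)|$
  on the chirp band, boxcar-smoothed over 0.5 Hz, band restricted to
  $[\max(f_0, 1), f_1]$ to avoid DC leakage; the resonant frequency is the
  argmax of the smoothed profile. Cells with $f_R > 2.2$ Hz classify as
  PT-like (strict inequality).
* **Membrane time constant**: double-exponential fit of the averaged
  post-pulse decay over a 50-ms window with both amplitudes constrained to
  the deflection's sign and both time constants bounded by the window. On
  a resonant membrane an unconstrained least-squares fit latches onto the
  h-current rebound (opposite sign, time constant far beyond the data);
  the constraints keep the slow component attached to the membrane
  charging modes. Passive oracle tests use longer windows.
* **Threshold detection**: central differences on a 3-point smoothed
  trace; the 20 mV/ms crossing is interpolated between samples, which is
  what makes the value invariant (±0.5 mV) to 10 vs 50 kHz digitization.
  Just-threshold searches bisect to a 1-pA bracket. The duration grid
  {1.5, 3, 6, 12, 25, 50, 100} ms spans the experimental range with the
  6-ms breakpoint included.
* **Exponential and Boltzmann fits**: Levenberg–Marquardt with log-spaced
  multi-starts, time constants ordered, ties broken by residual; traces
  are thinned to ≤500 points before fitting (no information loss for
  smooth exponentials). Activation fits are on conductance
  $G = I/(V-E_K)$ by default with $E_K = -96$ mV, both configurable.
* **Back-extrapolation**: a single exponential plus offset is fitted from
  three fast-time-constants after the peak to the end of the step and
  evaluated at the total-current peak time. If the fitted time constant is
  not well separated from the fast estimate the slow component is reported
  as absent rather than reconstructing the fast peak. The one-τ window
  rule is a warning rather than an error: the standard 500-ms protocol
  with a ~650-ms slow constant violates it by design.
* **Leak subtraction**: all traces are referenced to their holding
  baseline; single-step commands use classical scaled-trace subtraction,
  multi-segment commands apply the scaling sweeps' steady leak conductance
  to the command pointwise (identical in the linear case). One scaling set
  from −90 mV serves all three decomposition protocols, because small
  steps from a −20 mV holding would engage sustained-channel gating —
  exactly the contamination the method must avoid.
* **Comparison families**: Bonferroni correction is applied across the
  per-class feature battery (family size = number of features compared),
  declared explicitly in the pipeline configuration.

## What the generator does and does not emulate

Passing tests on simulated cohorts demonstrate that the analysis chain
recovers known ground truth and the programmed genotype contrasts at
realistic noise levels and cohort sizes. They do not certify performance
on real recordings, which additionally contain series-resistance and
space-clamp errors, electrode drift, seal instability, channel populations
beyond the seven modeled here, and animal-level nesting (the generator
draws cells independently; the pipeline pools cells exactly as the
original analysis did).

Two contrasts are known to be *under-expressed* by a single-compartment
generator and are documented limitations rather than bugs:

* **Threshold voltage.** The multi-millivolt Kv1-dependent shifts in
  spike-threshold voltage arise at the axon initial segment, where the
  local Kv1:Na ratio is far higher than at the soma. In a somatic
  compartment the Na activation steepness log-compresses any conductance
  scaling into sub-millivolt threshold shifts, which sit below the cohort
  noise floor. The just-threshold *current* contrast — the excitability
  phenotype proper — is robust (p < 10⁻⁵ at n = 15). Within-cell drug
  contrasts remain directionally correct: blocking the Kv1-like current
  lowers the long-pulse threshold current more than blocking the Kv4-like
  current.
* **Functional time constant.** The slow fitted component mixes the
  membrane charging mode with the h-current relaxation; the mixture
  compresses the knockout/wild-type contrast to ≈ 8%, so at n = 15 this
  comparison reproduces less reliably than the others.

## Problem sizes

The shipped test-suite runs the direction-pattern check at 20 simulation
seeds with 15 cells per cohort. The h-channel-block control pools 5
replicate cohort pairs into one comparison per feature: asserting
non-significance separately in every small replicate would test the type-I
error rate rather than the absence of an effect. It also runs type-I
calibration on 500 cohort pairs using the analytic small-signal
input resistance as the compared feature, Monte-Carlo fit recovery at 100
noise seeds, and the various oracles on single cells. These sizes were
chosen so the whole battery runs on one CPU in well under half an hour
while keeping every statistical check adequately powered; all of them are
arguments, not constants.
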