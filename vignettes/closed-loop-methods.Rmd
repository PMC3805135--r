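---
title: "Models and methods: dopamine, activity, and the IA:Ih ratio"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: dopamine, activity, and the IA:Ih ratio}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pyloop)
```

## The problem this package models

In the pyloric central pattern generator of the spiny lobster, the single
LP follower neuron fires one burst per cycle with a characteristic phase:
the delay from the last pacemaker (PD) spike to the first LP spike, divided
by the cycle period. That phase is set largely by the rate of
post-inhibitory rebound, which in turn reflects the balance of two
subthreshold conductances — the transient potassium current I_A (outward,
delays rebound) and the hyperpolarization-activated current I_h (inward,
accelerates it).

Micromolar dopamine perturbs this balance twice over, through two receptor
pools on the same neuron:

1. **Modulatory arm** (low-affinity D1 receptors, immediate): peak I_A
   falls to ~81% of baseline; network cycle period drops ~10%, LP burst
   duration ~30%, the mean within-burst ISI to 66%, and LP-on phase
   advances ~20%.
2. **Metaplastic arm** (high-affinity D1 receptors): dopamine does not
   change I_h by itself, but makes its maximal conductance
   activity-dependent. The dopamine-induced changes in slow-wave activity
   then drive G_max(I_h) down — to ~94% for the burst-duration change
   alone, ~87% when the cycle-frequency increase is included — which
   restores the I_A:I_h ratio (0.81/0.87 ≈ 0.93) and the firing phase.

The package implements the full measurement and modelling chain around this
loop on synthetic data, so every quantitative claim can be recomputed from
code alone.

## Synthetic recordings

`network_preset()` fixes the deterministic skeleton of a paired PD/LP
recording; `generate_network_recording()` realises it. Defaults: 1000 ms
period, 400 ms PD burst, 300 ms LP burst starting 250 ms after the last PD
spike (phase 0.25), 50 ms mean ISI, 2 ms spike jitter and 20 ms cycle
jitter. The absolute values are fixtures chosen to be order-of-magnitude
consistent with published traces (the papers show them only graphically);
the *ratios* under `da_preset()` (0.90, 0.70, 0.80, 0.66, 0.81) are the
quantitative content.

Two generator choices deserve comment:

- **Spike placement.** LP spikes span the full burst window, and the
  number of within-burst intervals per cycle follows a deterministic
  error-accumulation (Bresenham) scheme on `burst/ISI`. This makes the
  measured burst duration (first-to-last spike) track the burst-duration
  factor and the realized mean ISI track the ISI factor *simultaneously*,
  even though a fixed spike count could satisfy only one of the two (a 30%
  burst reduction with an ISI at 66% is not achievable with uniform spacing
  and an unchanged count). The default spike count is therefore
  `1 + burst/ISI` = 7 at baseline.
- **Jitter model.** Independent Gaussian perturbations of cycle anchors
  and of individual spikes, with ordering restored within bursts. Cycle
  anchors are jittered about their nominal positions (not as a random
  walk), so the mean period is unbiased. The source recordings suggest no
  particular noise model; this one is the simplest that exercises the
  averaging machinery. What the generator does *not* emulate: slow drifts,
  cycle-to-cycle correlations, missing or extra bursts, extracellular
  detection errors. Tests passing on this data show the pipeline's
  arithmetic is right, not that it is robust to every failure mode of real
  recordings.

## Voltage-clamp measurement chain

In-silico clamp traces are forward simulations of the channel models under
the commanded voltage plus ohmic leak and white Gaussian noise (default SD
0.05 nA per sample; no drift or oscillation artifacts). The h-current
protocol is the published one: holding −50 mV, 4 s steps from −60 to
−120 mV in 10 mV increments. Measurement follows the published procedure:

- **Exponential back-extrapolation** fits
  `I(t) = I0 + A (1 − e^{−t/τ})` over the step, skipping the first 5 ms
  (capacitive transient; the source is silent on the window, 5 ms is
  standard practice) and returns `A`, the slowly developing h-current with
  the instantaneous leak jump excluded. On noise-free model traces this is
  exact for any τ.
- **Peak-minus-leak** (the fallback used when oscillations corrupt a
  trace) takes the mean over the final 10% of the step minus the mean over
  2–10 ms post-onset. The two windows are our choices; the source names
  the quantities but not the windows. Both methods agree within 3% on
  clean traces with several τ of data.
- The A-current is measured exactly as published: a −90 mV deinactivating
  prepulse (200 ms) before a +60 mV step (400 ms), minus the same protocol
  with a −40 mV prepulse that keeps the current inactivated. The peak of
  the difference current is reported as current (not conductance),
  matching the original analysis.
- Conductances use `G = I/(V − V_rev)` with V_rev = −35 mV for I_h, and
  Boltzmann fits use `G(V) = G_max/(1 + e^{(V−V_1/2)/V_slope})`
  (positive slope = activation by hyperpolarization), initialised at
  `G_max = max |G|`, `V_1/2` at half-max, slope 8 mV.

The I_h kinetic parameters themselves (V_1/2 = −95 mV, slope 8 mV, bell
τ(V) peaking at 800 ms) are assumptions: the published τ values came from
separate recordings and are not printed. They are chosen so the current is
near steady state within the 4 s steps, which is all the analysis relies
on. Likewise the A-current's `m³h` scheme is the classic transient-current
form; the original work characterises the current but not a kinetic model.

## Gating, integration and the dynamic clamp

Gates follow `dm/dt = (m_∞(V) − m)/τ(V)` with
`m_∞ = 1/(1 + e^{(V−V_1/2)/V_slope})`, integrated by first-order forward
Euler — deliberately the same scheme as the original real-time dynamic
clamp, at the same 0.05 ms (20 kHz) step. The integrator is causal (the
current at sample n uses the state advanced from sample n−1) and clamps
gates to [0, 1]. At dt = τ/100 the Euler solution tracks the closed-form
exponential within 1%, converging at first order; `advance_gate()` warns
when dt exceeds τ. For the minutes-scale G_max relaxation we instead use
the exact exponential update, which is unconditionally stable, so the
plasticity clock can take coarse steps without error.

## The activity-dependence rule

`calibrate_ad_curve()` encodes the dopamine-enabled rule as

```
F(Δburst, Δfreq) = Boltzmann(Δburst) × f^(Δfreq/10)
```

Only two points of this surface are printed numbers, and the calibration
treats them as the anchors: F(−30, 0) = 0.94 and F(−30, +10) = 0.87, which
fixes f = 0.87/0.94 ≈ 0.926. Everything else is stated assumption: the top
asymptote 1.10 (the silent-preparation G_max increase is shown only
graphically), the bottom 0.85, the slope 20%. Complete silence
(Δburst ≤ −100) is pinned at the top as its own anchor rather than read
off the smooth curve. Nanomolar mode re-anchors the curve through
F(0, 0) = 1 (mimicked baseline activity produces no change) and has no
calibrated frequency factor; mode `"none"` is the identity — the central
gating claim, no plasticity without dopamine, is hard-coded rather than
emergent.

Spike activity gates the rule: a lumped spike-mimicking depolarization
forces F = 1 exactly (the measured fold was 1.008 ± 0.010, i.e. no
change), while patterned spikes leave the target intact but multiply the
relaxation τ by `patterned_tau_multiplier` (default 10). The relaxation τ
itself (3 min) is an assumption pinned only by the observation that the
change is complete by 10 min — 3 min puts 10 min at ~96% of the way.
Whether burst-duration and frequency effects are truly separable and
multiplicative is not established by the data; the factorised form is the
simplest rule consistent with the two anchors.

## Closed-loop experiments

`run_clamp_experiment()` composes the pieces: measure both currents through
the full in-silico pipeline at t = 0, apply dopamine (I_A conductance ×
0.81; metaplasticity on, driven by the activity index implied by the
command waveform), re-measure at the requested times. With the combined
burst+frequency command the emulation lands at I_A ≈ 0.81, I_h ≈ 0.87 at
10 min, ratio ≈ 0.93 — and over an hour the ratio stays within 10% of
baseline while each current differs from baseline by well over 13%.

`run_network_experiment()` runs the minimal biophysical version: a
single-compartment neuron (leak + I_A + I_h) inhibited each cycle by a
square synaptic pulse standing in for the pacemaker burst. Spiking is a
threshold-crossing proxy (−52 mV): burst onset = first suprathreshold
sample after release, burst duration = suprathreshold time. This is
deliberate — the phase metrics need spike timing only, and the original
silent-preparation experiments show slow waves suffice to drive the rule.
Channel dynamics run at 0.05 ms; the plasticity state updates every
`update_min` (default 0.5 min) from burst metrics averaged over 3 cycles,
a quasi-static split justified by the three-orders-of-magnitude gap
between the channel and plasticity time scales.

The default membrane/channel parameters were tuned by grid search
(`tools/tune_network.R`) under three constraints: a rebound latency well
inside the release window at baseline; finite, monotone latencies across a
±30% conductance grid (so the loop cannot silence the cell); and a
15–25% phase advance under the dopamine condition. The tuning targets the
qualitative regime, not any measured value. Within it, the A-current's
activation is placed right at the threshold proxy (V_1/2 = −50 mV, slope
−4 mV, τ 3 ms) so it acts as a brake exactly where crossings happen, and
its inactivation (τ 120 ms) is clearly faster than the h-gate decay
(τ(V) ~ 900 ms near threshold) so the brake releases before the push
fades — the race that makes latency a graded function of both
conductances.

Because the rebound neuron fires (patterned) spikes, its plasticity runs
with the slowed patterned-spike kinetics by default. The simulation then
reproduces the full temporal signature: phase advance to ~0.84–0.88 of
baseline by 5–10 min, recovery through baseline over tens of minutes, and
— with the dynamic-clamp add-back engaged at +10 min — no recovery at all.
The add-back implements `(1 − fold) × G_max0 × m × (V − E_rev)` with the
*current* metaplastic fold, i.e. it cancels the plastic change
continuously and exactly; trajectories with and without it are identical
until it engages.

**Known limitation.** In this model the rebound latency is set by channel
kinetics and is almost independent of the cycle period, whereas the phase
is latency/period. When the loop restores the conductance ratio, the
latency returns near its baseline value while the period is 10% shorter,
so the phase fold settles ~10–14% *above* 1 rather than exactly at 1. The
simulation therefore shows advance-then-recovery with a mild overshoot;
exact phase constancy would need period-tracking mechanisms (synaptic
depression dynamics, waveform scaling) that are outside this model's
scope, as are the full 14-neuron network, graded transmission, calcium
dynamics and receptor signalling cascades.

## Problem sizes and reproducibility

The test suite and the acceptance script run at desk scale: 10-minute
synthetic recordings (~600 cycles per condition) for the metrics targets,
single 7-step clamp sweeps per measurement (dt 0.5 ms for I_h, 0.1 ms for
I_A), and 60–100 simulated minutes of the network at dt 0.05 ms. All
randomness flows from one integer seed through named substreams per
module; identical seed and configuration give byte-identical outputs, and
zero-jitter generation is deterministic regardless of seed.
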