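# pyloop

Neuromodulators reconfigure rhythmic circuits, but unchecked modulation can
destabilise them. In the crustacean pyloric central pattern generator,
micromolar dopamine reduces the transient potassium current I_A of the
lateral pyloric (LP) follower neuron, advancing its firing phase — and at
the same time, acting through high-affinity D1 receptors, it makes the
maximal conductance of the hyperpolarization-activated current I_h
*activity-dependent*. The dopamine-induced changes in slow-wave activity
(shorter bursts, faster cycles) then drive a compensatory reduction of I_h
that restores the I_A:I_h ratio and the neuron's firing phase: a closed
feedback loop. `pyloop` implements the computational content of that story
for simulation and analysis:

- **Synthetic data**: paired pacemaker (PD) / follower (LP) spike trains
  with configurable period, burst durations, LP-on delay, within-burst ISI
  and jitter; clamp command waveforms (slow-wave steps with lumped or
  patterned spike mimicry); noisy voltage-clamp current traces
  forward-simulated from known channel models.
- **Burst and phase metrics**: ISI-threshold burst detection, cycle period
  `a` (last PD spike to last PD spike), LP-on delay `b`, LP-on phase `b/a`,
  burst duration `c`, with 10-cycle averaging and fold-change reporting.
- **Voltage-clamp analysis**: the h-current protocol (4 s steps, −60 to
  −120 mV), steady-state amplitude by single-exponential
  back-extrapolation `I(t) = I0 + A(1 − e^{−t/τ})` (or peak-minus-leak as
  fallback), the A-current prepulse leak-subtraction protocol (−90 vs −40
  mV prepulse, +60 mV test), chord conductance `G = I/(V − V_rev)`, and
  first-order Boltzmann fits `G(V) = G_max / (1 + e^{(V−V_1/2)/V_slope})`.
- **Channel models**: dynamic-clamp style h-current (`I = G_max m (V −
  E_rev)`, E_rev = −35 mV, forward-Euler gating at 20 kHz) and a classic
  `m³h` transient A-current.
- **Metaplasticity**: the dopamine-enabled activity-dependence rule — a
  Boltzmann curve over percent burst-duration change anchored at
  (−30%, 0.94), a cycle-frequency factor 0.87/0.94 per +10%, total gating
  by lumped spike mimicry, slowed kinetics under patterned spikes, and
  first-order relaxation of G_max toward its activity-determined target.
- **Closed-loop experiments**: in-silico clamp emulations that measure both
  currents through the full pipeline while the rule runs, and a minimal
  post-inhibitory-rebound neuron driven by a pacemaker that shows the phase
  advance, its slow recovery, and the loss of recovery when a dynamic-clamp
  add-back current cancels the plastic change.

## Worked example

Calibrate the activity-dependence curve, then emulate the clamp experiment
in which the recurring voltage step mimics both the 30% burst-duration
decrease and the 10% cycle-frequency increase that dopamine produces:

```r
library(pyloop)

curve <- calibrate_ad_curve("micromolar")
curve
#> <ad_curve: micromolar>
#>   Boltzmann top 1.1 / bottom 0.85, x_half -41.5%, x_slope 20%
#>   freq factor per +10%: 0.9255; tau_ad 3 min (x10 patterned)

cfg <- clamp_experiment_config(
  command          = command_waveform(step_ms = 210, cycle_period_ms = 900),
  baseline_command = command_waveform(step_ms = 300, cycle_period_ms = 1000))
res <- run_clamp_experiment(cfg)
res[, c("time_min", "ia_fold", "ih_peak_fold", "ratio_fold")]
#>   time_min ia_fold ih_peak_fold ratio_fold
#> 1        0   1.000        1.000      1.000
#> 2       10   0.811        0.867      0.934
```

By 10 minutes the A-current has fallen to 81% of baseline (the immediate
modulatory arm) and the measured peak h-current to ~87% (the
activity-dependent arm), so the I_A:I_h ratio is back within ~7% of its
starting value — the closed loop at work. `autoplot(res)` draws the
fold-change time courses, and `tidy(res)` / `glance(res)` give long-format
and final-state summaries. `run_network_experiment(rebound_neuron_config())`
runs the rebound-neuron version: phase advance by ~16–20% after dopamine,
recovery over tens of minutes as I_h is traded against I_A, and no recovery
when `addback = TRUE`.

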