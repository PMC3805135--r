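# Shared fixtures: presets and small helpers used across test files.

quiet_preset <- function(...) {
  network_preset(spike_jitter_sd_ms = 0, cycle_jitter_sd_ms = 0, ...)
}

default_leak <- list(g_uS = 0.05, e_mV = -50)

# metrics pipeline: recording -> per-cycle metrics
recording_metrics <- function(rec, max_isi_ms = NULL) {
  b <- pyloop:::recording_bursts(rec, max_isi_ms = max_isi_ms)
  cycle_metrics(b$PD, b$LP)
}

# window-averaged column means over a whole recording
summary_metrics <- function(rec, n = 10) {
  wa <- windowed_average(recording_metrics(rec), n = n)
  colMeans(wa[, c("a_ms", "b_ms", "c_ms", "lp_on_phase", "mean_isi_ms",
                  "spikes_per_burst")])
}

# closed-form first-order gate relaxation, the independent oracle for the
# forward-Euler integrator
gate_closed_form <- function(t, v, m0, v_half, v_slope, tau) {
  minf <- 1 / (1 + exp((v - v_half) / v_slope))
  minf + (m0 - minf) * exp(-t / tau)
}
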