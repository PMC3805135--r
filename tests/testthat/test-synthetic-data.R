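test_that("zero-jitter generation is exactly periodic and matches the preset", {
  rec <- generate_network_recording(quiet_preset(), 20000, seed = 1)
  pd <- rec$spike_time_ms[rec$cell_id == "PD"]
  lp <- rec$spike_time_ms[rec$cell_id == "LP"]
  expect_false(is.unsorted(pd, strictly = TRUE))
  expect_false(is.unsorted(lp, strictly = TRUE))

  wins <- burst_windows(rec)
  expect_equal(sum(wins$cell_id == "PD"), 20)  # 20 s at 1 s period
  pd_last <- wins$offset_ms[wins$cell_id == "PD"]
  expect_equal(diff(pd_last), rep(1000, 19))

  # deterministic: seed is irrelevant without jitter
  rec2 <- generate_network_recording(quiet_preset(), 20000, seed = 99)
  expect_identical(rec$spike_time_ms, rec2$spike_time_ms)

  # LP bursts span the configured window at the configured phase
  lp_wins <- wins[wins$cell_id == "LP", ]
  expect_equal(lp_wins$offset_ms - lp_wins$onset_ms,
               rep(300, nrow(lp_wins)))
  expect_equal(lp_wins$onset_ms[1] %% 1000, 250)
})

test_that("same seed and config give identical jittered output", {
  p <- network_preset()
  a <- generate_network_recording(p, 15000, seed = 42)
  b <- generate_network_recording(p, 15000, seed = 42)
  expect_identical(a$spike_time_ms, b$spike_time_ms)
  c <- generate_network_recording(p, 15000, seed = 43)
  expect_false(identical(a$spike_time_ms, c$spike_time_ms))
})

test_that("jittered mean cycle period converges to the preset", {
  p <- network_preset(cycle_jitter_sd_ms = 20, spike_jitter_sd_ms = 0)
  rec <- generate_network_recording(p, 70000, seed = 7)
  pd_last <- burst_windows(rec) |> dplyr::filter(cell_id == "PD")
  periods <- diff(pd_last$offset_ms)
  expect_gte(length(periods), 60)
  expect_lt(abs(mean(periods) - 1000) / 1000, 0.01)
})

test_that("realized metric ratios converge to 1 as jitter shrinks", {
  target <- c(a_ms = 1000, c_ms = 300, b_ms = 250, mean_isi_ms = 50)
  for (sd in c(10, 1)) {
    p <- network_preset(cycle_jitter_sd_ms = sd, spike_jitter_sd_ms = sd / 10)
    m <- summary_metrics(generate_network_recording(p, 60000, seed = 5))
    dev <- abs(m[names(target)] / target - 1)
    expect_lt(max(dev), 0.05 * sd)
  }
  m0 <- summary_metrics(generate_network_recording(quiet_preset(), 60000, seed = 5))
  expect_equal(unname(m0[names(target)]), unname(target), tolerance = 1e-10)
})

test_that("invariant-violating presets fail naming the offending field", {
  expect_error(network_preset(lp_on_delay_ms = 800), "lp_on_delay_ms")
  expect_error(network_preset(lp_mean_isi_ms = 100, lp_spikes_per_burst = 7),
               "lp_mean_isi_ms")
  expect_error(network_preset(cycle_period_ms = -1), "cycle_period_ms")
  expect_error(generate_network_recording(network_preset(), 5000), "10 cycles")
})

test_that("dopamine preset scales period, burst, phase and ISI as configured", {
  base <- network_preset()
  da <- apply_da_preset(base, da_preset())
  expect_equal(da$cycle_period_ms, 900)
  expect_equal(da$lp_burst_ms, 210)
  expect_equal(da$lp_mean_isi_ms, 33)
  # delay set from scaled phase: 0.25 * 0.8 * 900
  expect_equal(da$lp_on_delay_ms, 180)

  # identity preset changes nothing
  ident <- apply_da_preset(base, da_preset(1, 1, 1, 1, 1))
  expect_equal(ident[names(ident) != "lp_spikes_per_burst"],
               base[names(base) != "lp_spikes_per_burst"])

  # scaling that breaks an invariant errors
  expect_error(apply_da_preset(base, da_preset(lp_burst_factor = 3)))
})

test_that("DA-scaled recordings reproduce the burst-duration and ISI folds", {
  base <- quiet_preset()
  da <- apply_da_preset(base, da_preset())
  m0 <- summary_metrics(generate_network_recording(base, 30000, seed = 2))
  m1 <- summary_metrics(generate_network_recording(da, 30000, seed = 2))
  expect_equal(unname(m1["c_ms"] / m0["c_ms"]), 0.70, tolerance = 0.02)
  expect_equal(unname(m1["mean_isi_ms"] / m0["mean_isi_ms"]), 0.66,
               tolerance = 0.02)
  expect_equal(unname(m1["a_ms"] / m0["a_ms"]), 0.90, tolerance = 1e-6)
})

test_that("command waveforms render steps, duty cycle and spike mimicry", {
  cmd <- generate_command(command_waveform(step_ms = 300, cycle_period_ms = 1000,
                                           n_cycles = 3), dt_ms = 0.5)
  expect_equal(max(cmd$time_ms), 3000 - 0.5)
  expect_equal(mean(cmd$v_mV == -40), 0.3, tolerance = 1e-3)  # 30% duty

  lump <- generate_command(command_waveform(spike_mode = "lumped",
                                            spike_count = 6, spike_width_ms = 2,
                                            n_cycles = 2), dt_ms = 0.05)
  runs <- rle(lump$v_mV[lump$time_ms < 1000] == 40)
  expect_equal(sum(runs$lengths[runs$values]) * 0.05, 12)  # one 12 ms step

  pat <- generate_command(command_waveform(spike_mode = "patterned",
                                           spike_count = 6, spike_width_ms = 2,
                                           spike_isi_ms = 33, n_cycles = 1),
                          dt_ms = 0.05)
  at_peak <- rle(pat$v_mV == 40)
  expect_equal(sum(at_peak$values), 6)  # six distinct depolarizations
  gaps <- at_peak$lengths[!at_peak$values]
  expect_equal(gaps[1:5] * 0.05, rep(33, 5))  # inter-depolarization gap

  expect_error(command_waveform(spike_mode = "patterned", spike_count = 6,
                                spike_width_ms = 2, spike_isi_ms = 100,
                                step_ms = 300), "span")
})

test_that("clamp traces reproduce ohmic leak and channel steady states", {
  prot <- step_protocol(data.frame(prepulse_mV = NA, prepulse_ms = 0,
                                   test_mV = -120, test_ms = 4000),
                        holding_mV = -50)
  leak_only <- generate_clamp_trace(list(), default_leak, prot,
                                    noise_sd_nA = 0, dt_ms = 0.5)[[1]]
  win <- leak_only$time_ms >= 200
  expect_equal(unique(round(leak_only$i_nA[win], 9)), 0.05 * (-120 + 50))

  ch <- h_channel(g_max_uS = 0.1)
  tr <- generate_clamp_trace(list(ch), default_leak, prot,
                             noise_sd_nA = 0, dt_ms = 0.5)[[1]]
  expected_late <- 0.05 * (-120 + 50) +
    0.1 * gate_steady_state(-120, -95, 8) * (-120 + 35)
  expect_equal(tail(tr$i_nA, 1), expected_late, tolerance = 0.005)
})

test_that("noisy traces still yield the steady-state amplitude within 2%", {
  ch <- h_channel(g_max_uS = 0.1)
  prot <- step_protocol(data.frame(prepulse_mV = NA, prepulse_ms = 0,
                                   test_mV = -120, test_ms = 4000),
                        holding_mV = -50)
  clean <- generate_clamp_trace(list(ch), default_leak, prot, 0, dt_ms = 0.5)[[1]]
  noisy <- generate_clamp_trace(list(ch), default_leak, prot, 0.05,
                                seed = 3, dt_ms = 0.5)[[1]]
  a_clean <- measure_ih_peak(clean)$steady_state_nA
  a_noisy <- measure_ih_peak(noisy)$steady_state_nA
  expect_lt(abs(a_noisy / a_clean - 1), 0.02)
})
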