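base_cmd <- command_waveform(step_ms = 300, cycle_period_ms = 1000)
da_burst_only <- command_waveform(step_ms = 210, cycle_period_ms = 1000)
da_combined <- command_waveform(step_ms = 210, cycle_period_ms = 900)

test_that("burst-only clamp emulation reduces the h-current by ~6% at 10 min", {
  cfg <- clamp_experiment_config(command = da_burst_only,
                                 baseline_command = base_cmd)
  res <- run_clamp_experiment(cfg)
  expect_equal(res$ih_gmax_fold[res$time_min == 10], 0.94, tolerance = 0.02)
  expect_equal(attr(res, "target_fold"), 0.94, tolerance = 1e-9)
})

test_that("adding the frequency increase deepens the h-current fold to ~0.87", {
  cfg <- clamp_experiment_config(command = da_combined,
                                 baseline_command = base_cmd)
  res <- run_clamp_experiment(cfg)
  r10 <- res[res$time_min == 10, ]
  expect_equal(r10$ih_peak_fold, 0.87, tolerance = 0.03)
  expect_equal(r10$ia_fold, 0.81, tolerance = 0.04)
  expect_equal(r10$ratio_fold, 0.81 / 0.87, tolerance = 0.05)
})

test_that("a lumped spike mimic abolishes the h-current change", {
  cfg <- clamp_experiment_config(
    command = command_waveform(step_ms = 210, cycle_period_ms = 900,
                               spike_mode = "lumped"),
    baseline_command = base_cmd)
  res <- run_clamp_experiment(cfg)
  expect_equal(res$ih_peak_fold[res$time_min == 10], 1.0, tolerance = 0.02)
})

test_that("ratio restoration: both currents change while their ratio holds", {
  cfg <- clamp_experiment_config(command = da_combined,
                                 baseline_command = base_cmd,
                                 duration_min = 60,
                                 measure_times_min = c(0, 60))
  res <- run_clamp_experiment(cfg)
  final <- res[res$time_min == 60, ]
  expect_lt(abs(final$ratio_fold - 1), 0.10)
  expect_gte(1 - final$ia_fold, 0.13)
  expect_gte(1 - final$ih_peak_fold, 0.13)
})

test_that("without dopamine the loop is open: h-current pinned, ratio tracks IA", {
  cfg <- clamp_experiment_config(command = da_combined,
                                 baseline_command = base_cmd,
                                 da_mode = "none")
  res <- run_clamp_experiment(cfg)
  r10 <- res[res$time_min == 10, ]
  expect_equal(r10$ih_gmax_fold, 1, tolerance = 0.02)
  expect_equal(r10$ratio_fold, r10$ia_fold / r10$ih_peak_fold, tolerance = 1e-12)
  expect_equal(r10$ratio_fold, r10$ia_fold, tolerance = 0.03)
})

test_that("the dynamic-clamp prediction is a pure curve lookup", {
  curve <- calibrate_ad_curve("micromolar")
  expect_equal(predict_metaplastic_fold(curve, -30), 0.94, tolerance = 1e-9)
  expect_equal(predict_metaplastic_fold(calibrate_ad_curve("nanomolar"), 0), 1,
               tolerance = 1e-9)
  expect_equal(predict_metaplastic_fold(curve, -100), curve$top)
})

test_that("rebound latency is monotone in each conductance and ratio-invariant", {
  cfg <- rebound_neuron_config()
  ga0 <- cfg$ia$g_max_uS
  gh0 <- cfg$ih$g_max_uS
  sc <- c(0.7, 1, 1.3)
  lat_a <- vapply(sc, function(s) rebound_latency(s * ga0, gh0, cfg), numeric(1))
  lat_h <- vapply(sc, function(s) rebound_latency(ga0, s * gh0, cfg), numeric(1))
  expect_true(all(diff(lat_a) > 0))  # more A-current delays rebound
  expect_true(all(diff(lat_h) < 0))  # more h-current speeds it

  # scaling both by the dopamine fold moves latency far less than either alone
  l0 <- rebound_latency(ga0, gh0, cfg)
  l_both <- rebound_latency(0.81 * ga0, 0.81 * gh0, cfg)
  l_a <- rebound_latency(0.81 * ga0, gh0, cfg)
  l_h <- rebound_latency(ga0, 0.81 * gh0, cfg)
  expect_lt(abs(l_both - l0), abs(l_a - l0))
  expect_lt(abs(l_both - l0), abs(l_h - l0))
})

test_that("a silent configuration raises a diagnostic error", {
  cfg <- rebound_neuron_config()
  expect_error(rebound_latency(10 * cfg$ia$g_max_uS, 0.05, cfg), "silent")
})

test_that("the network shows phase advance then recovery; no dopamine, no drift", {
  res <- run_network_experiment(rebound_neuron_config(), duration_min = 100,
                                update_min = 1)
  at10 <- res$phase_fold[res$time_min == 10]
  expect_lt(at10, 0.92)                     # clear early advance
  final <- res$phase_fold[res$time_min == 100]
  expect_gt(final, 0.95)                    # phase recovered
  expect_lt(abs(final - 1), abs(min(res$phase_fold) - 1) + 0.03)
  # the h-current was traded for the A-current along the way
  expect_lt(res$gh_fold[res$time_min == 100], 0.9)

  ctrl <- run_network_experiment(
    rebound_neuron_config(ia_factor = 1, period_factor = 1,
                          curve = calibrate_ad_curve("none")),
    duration_min = 20, update_min = 2)
  expect_true(all(abs(ctrl$phase_fold - 1) < 0.02))
  expect_true(all(abs(ctrl$gh_fold - 1) < 0.02))
})

test_that("dynamic-clamp add-back prevents phase recovery", {
  on <- run_network_experiment(rebound_neuron_config(addback = TRUE),
                               duration_min = 60, update_min = 1)
  off <- run_network_experiment(rebound_neuron_config(),
                                duration_min = 60, update_min = 1)
  # identical before the add-back engages at 10 min
  expect_equal(on$phase_fold[on$time_min < 10],
               off$phase_fold[off$time_min < 10], tolerance = 1e-9)
  # afterwards the add-back holds the phase advanced while control recovers
  expect_true(all(on$phase_fold[on$time_min >= 15] < 0.9))
  expect_gt(off$phase_fold[off$time_min == 60], 0.95)
})
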