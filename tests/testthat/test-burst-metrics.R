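test_that("ISI-threshold burst detection groups and filters spikes", {
  b <- detect_bursts(c(0, 10, 20, 500, 510), max_isi_ms = 100, min_spikes = 2)
  expect_equal(nrow(b), 2)
  expect_equal(b$first_spike_ms, c(0, 500))
  expect_equal(b$n_spikes, c(3L, 2L))

  expect_equal(nrow(detect_bursts(5, max_isi_ms = 100, min_spikes = 2)), 0)
  expect_equal(nrow(detect_bursts(numeric(), max_isi_ms = 100)), 0)
  expect_error(detect_bursts(c(10, 5), max_isi_ms = 100), "sorted")
})

test_that("bursts detected on zero-jitter trains match generator windows", {
  rec <- generate_network_recording(quiet_preset(), 20000, seed = 1)
  lp <- detect_bursts(rec$spike_time_ms[rec$cell_id == "LP"],
                      max_isi_ms = 150)
  wins <- burst_windows(rec) |> dplyr::filter(cell_id == "LP")
  expect_equal(lp$first_spike_ms, wins$onset_ms)
  expect_equal(lp$last_spike_ms, wins$offset_ms)
  expect_equal(lp$n_spikes, wins$n_spikes)
})

test_that("cycle metrics implement the last-PD-spike conventions", {
  pd <- detect_bursts(c(980, 990, 1000, 1980, 1990, 2000), max_isi_ms = 50)
  lp <- detect_bursts(c(1250, 1300, 1350), max_isi_ms = 100)
  cm <- cycle_metrics(pd, lp)
  expect_equal(cm$a_ms, 1000)
  expect_equal(cm$b_ms, 250)
  expect_equal(cm$lp_on_phase, 0.25)
  expect_equal(cm$c_ms, 100)
  expect_equal(cm$lp_off_delay_ms, 350)
})

test_that("cycles without an assignable LP burst are flagged, many error", {
  pd <- detect_bursts(c(990, 1000, 1990, 2000, 2990, 3000), max_isi_ms = 50)
  lp_one <- detect_bursts(c(1250, 1300), max_isi_ms = 100)
  cm <- cycle_metrics(pd, lp_one)
  expect_equal(cm$lp_missing, c(FALSE, TRUE))

  # no burst structure at all: a shuffled LP train collapses to one burst
  # far outside the cycles, so most cycles lack an assignable burst
  lp_shuffled <- detect_bursts(seq(5000, 5100, by = 10), max_isi_ms = 100)
  expect_error(cycle_metrics(pd, lp_shuffled), "mis-paired|burst structure")
})

test_that("phase is invariant under uniform time rescaling", {
  rec <- generate_network_recording(network_preset(), 20000, seed = 8)
  cm1 <- recording_metrics(rec)
  scaled <- rec
  scaled$spike_time_ms <- scaled$spike_time_ms * 3.7
  b <- split(scaled$spike_time_ms, scaled$cell_id) |>
    lapply(detect_bursts, max_isi_ms = 3 * 50 * 3.7)
  cm2 <- cycle_metrics(b$PD, b$LP)
  expect_equal(cm2$lp_on_phase, cm1$lp_on_phase, tolerance = 1e-12)
})

test_that("windowed averages reduce each field arithmetically", {
  cm <- recording_metrics(generate_network_recording(quiet_preset(), 12000, seed = 1))
  wa <- windowed_average(cm, n = 10)
  expect_equal(nrow(wa), 1)
  expect_equal(wa$a_ms, 1000)
  expect_equal(wa$lp_on_phase, 0.25)

  fake <- cm[1:10, ]
  fake$a_ms <- c(rep(900, 5), rep(1100, 5))
  expect_equal(windowed_average(fake, n = 10)$a_ms, 1000)
  expect_error(windowed_average(cm[1:4, ], n = 10), "at least")
})

test_that("jittered window averages sit near the preset within sampling error", {
  p <- network_preset(cycle_jitter_sd_ms = 20, spike_jitter_sd_ms = 2)
  cm <- recording_metrics(generate_network_recording(p, 15000, seed = 7))
  wa <- windowed_average(cm, n = 10)
  # SE of a 10-cycle mean of periods with SD ~ sqrt(2)*20 ms
  expect_lt(abs(wa$a_ms[1] - 1000), 3 * sqrt(2) * 20 / sqrt(10))
})

test_that("fold-change normalizes to the reference row and is idempotent", {
  df <- tibble::tibble(time_min = c(0, 10, 60),
                       lp_on_phase = c(0.25, 0.20, 0.25),
                       a_ms = c(1000, 900, 900))
  f <- fold_change(df, c(lp_on_phase, a_ms), reference_time = 0)
  expect_equal(f$lp_on_phase, c(1, 0.8, 1))
  expect_equal(f$a_ms, c(1, 0.9, 0.9))
  expect_equal(fold_change(f, c(lp_on_phase, a_ms), reference_time = 0), f)

  const <- fold_change(tibble::tibble(time_min = 0:3, x = rep(2, 4)), x)
  expect_equal(const$x, rep(1, 4))

  bad <- tibble::tibble(time_min = c(0, 1), x = c(0, 5))
  expect_error(fold_change(bad, x, reference_time = 0), "zero")
})
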