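test_that("the h-current protocol matches the published step series", {
  p <- ih_protocol()
  expect_equal(nrow(p), 7)
  expect_equal(p$test_mV, seq(-60, -120, by = -10))
  expect_equal(unique(p$test_ms), 4000)
  expect_equal(attr(p, "holding_mV"), -50)
  expect_equal(attr(p, "inter_step_ms"), 6000)

  ia <- ia_protocol(TRUE)
  expect_equal(ia$prepulse_mV, -90)
  expect_equal(ia$prepulse_ms, 200)
  expect_equal(ia$test_mV, 60)
  expect_equal(ia$test_ms, 400)
  expect_equal(ia_protocol(FALSE)$prepulse_mV, -40)
})

test_that("exponential back-extrapolation is exact on noise-free model traces", {
  for (tau in c(200, 800)) {
    t <- seq(0, 4000, by = 0.5)
    tr <- sampled_trace(t, -2 + (-5) * (1 - exp(-t / tau)), kind = "current",
                        meta = list(test_onset_ms = 0, test_offset_ms = 4000,
                                    test_mV = -120))
    fit <- measure_ih_peak(tr)
    expect_equal(fit$steady_state_nA, -5, tolerance = 1e-6)
    expect_equal(fit$tau_ms, tau, tolerance = 1e-4)
    expect_equal(fit$offset_nA, -2, tolerance = 1e-6)
  }
})

test_that("exp-fit and peak-minus-leak agree within 3% given ample data", {
  ch <- h_channel(g_max_uS = 0.1)
  # tau at -120 mV is ~424 ms, so a 4 s step holds >9 tau of data
  tr <- generate_clamp_trace(list(ch), default_leak,
                             ih_protocol(), noise_sd_nA = 0.02, seed = 11,
                             dt_ms = 0.5)[[7]]
  a_fit <- measure_ih_peak(tr, method = "exp_fit")$steady_state_nA
  a_sub <- measure_ih_peak(tr, method = "peak_minus_leak")$steady_state_nA
  expect_lt(abs(a_fit - a_sub) / abs(a_fit), 0.03)
})

test_that("an rmse ceiling redirects to the subtraction method", {
  t <- seq(0, 4000, by = 0.5)
  osc <- -2 + (-5) * (1 - exp(-t / 800)) + 0.8 * sin(2 * pi * t / 700)
  tr <- sampled_trace(t, osc, kind = "current",
                      meta = list(test_onset_ms = 0, test_offset_ms = 4000,
                                  test_mV = -120))
  expect_error(measure_ih_peak(tr, rmse_max_nA = 0.1), "peak_minus_leak")
  expect_no_error(measure_ih_peak(tr, method = "peak_minus_leak"))
})

test_that("prepulse leak subtraction recovers the A-current peak", {
  ch <- a_channel(g_max_uS = 0.6)
  test <- generate_clamp_trace(list(ch), default_leak, ia_protocol(TRUE),
                               noise_sd_nA = 0, dt_ms = 0.1)[[1]]
  lk <- generate_clamp_trace(list(ch), default_leak, ia_protocol(FALSE),
                             noise_sd_nA = 0, dt_ms = 0.1)[[1]]
  # identical traces give zero difference current
  expect_equal(measure_ia_peak(test, test), 0)

  peak <- measure_ia_peak(test, lk)
  # oracle: peak of g * m(t)^3 * h(t) * (V - E) along the step, from the
  # closed-form gate relaxations at constant +60 mV
  tt <- seq(0, 400, by = 0.1)
  m <- gate_closed_form(tt, 60, gate_steady_state(-90, -30, -10), -30, -10, 10)
  h0 <- gate_steady_state(-90, -60, 6)
  h <- gate_closed_form(tt, 60, h0, -60, 6, 80)
  h_leakpre <- gate_closed_form(tt, 60, gate_steady_state(-40, -60, 6), -60, 6, 80)
  m_leakpre <- gate_closed_form(tt, 60, gate_steady_state(-40, -30, -10), -30, -10, 10)
  oracle <- max(0.6 * (m^3 * h - m_leakpre^3 * h_leakpre) * (60 + 80))
  expect_equal(peak, oracle, tolerance = 0.02 * oracle)

  short <- test[1:100, ]
  expect_error(measure_ia_peak(short, lk), "length")
})

test_that("a conductance-scaled A-current yields the same measured fold", {
  mk <- function(g, seed) {
    ch <- a_channel(g_max_uS = g)
    tt <- generate_clamp_trace(list(ch), default_leak, ia_protocol(TRUE),
                               noise_sd_nA = 0.05, seed = seed, dt_ms = 0.1)[[1]]
    lk <- generate_clamp_trace(list(ch), default_leak, ia_protocol(FALSE),
                               noise_sd_nA = 0.05, seed = seed + 17, dt_ms = 0.1)[[1]]
    measure_ia_peak(tt, lk)
  }
  ratio <- mk(0.6 * 0.81, 2) / mk(0.6, 1)
  expect_equal(ratio, 0.81, tolerance = 0.03)
})

test_that("conductance conversion is exact arithmetic and invertible", {
  expect_equal(to_conductance(-8.5, -120, -35), 0.1)
  expect_equal(to_conductance(0, -120, -35), 0)
  g <- to_conductance(-4.2, -100, -35)
  expect_equal(g * (-100 + 35), -4.2)
  expect_error(to_conductance(1, -35, -35), "undefined")
})

test_that("Boltzmann fits recover known parameters, noisy and noise-free", {
  v <- seq(-60, -120, by = -10)
  g_true <- 0.1 / (1 + exp((v + 95) / 8))
  bf <- fit_boltzmann(tibble::tibble(test_mV = v, g_uS = g_true))
  expect_equal(bf$gmax_uS, 0.1, tolerance = 1e-3)
  expect_equal(bf$v_half_mV, -95, tolerance = 0.01)
  expect_gt(bf$v_slope_mV, 0)  # activation by hyperpolarization: + slope

  # repeated noisy fits: v_half within 2 mV
  set.seed(42)
  vh <- replicate(20, {
    g <- g_true * (1 + rnorm(length(v), 0, 0.05))
    fit_boltzmann(tibble::tibble(test_mV = v, g_uS = g))$v_half_mV
  })
  expect_lt(mean(abs(vh + 95)), 2)

  expect_error(fit_boltzmann(tibble::tibble(test_mV = v[1:3], g_uS = g_true[1:3])),
               "at least 4")
})

test_that("fit recovery improves monotonically as noise shrinks", {
  v <- seq(-60, -120, by = -10)
  g_true <- 0.1 / (1 + exp((v + 95) / 8))
  err_at <- function(noise_sd) {
    set.seed(7)
    mean(replicate(30, {
      g <- g_true * (1 + rnorm(length(v), 0, noise_sd))
      abs(fit_boltzmann(tibble::tibble(test_mV = v, g_uS = g))$gmax_uS - 0.1)
    }))
  }
  errs <- vapply(c(0.10, 0.03, 0.01), err_at, numeric(1))
  expect_true(all(diff(errs) < 0))
})
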