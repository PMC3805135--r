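#' Voltage-step protocol
#'
#' A tibble of clamp steps (optional prepulse, then test step) plus holding
#' potential and inter-step interval, the container consumed by
#' [generate_clamp_trace()] and the measurement functions.
#'
#' @param steps Data frame with columns `prepulse_mV`, `prepulse_ms`,
#'   `test_mV`, `test_ms` (use `NA`/0 prepulse fields for plain steps).
#' @param holding_mV Holding potential, mV.
#' @param inter_step_ms Interval between steps, ms.
#' @return A tibble of class `step_protocol`.
#' @export
step_protocol <- function(steps, holding_mV, inter_step_ms = 6000) {
  need <- c("prepulse_mV", "prepulse_ms", "test_mV", "test_ms")
  if (!all(need %in% names(steps)) || nrow(steps) == 0L) {
    abort("`steps` must be a non-empty data frame with prepulse/test columns.")
  }
  if (any(steps$test_ms <= 0)) abort("`test_ms` must be positive.")
  structure(as_tibble(steps),
            class = c("step_protocol", class(as_tibble(steps))),
            holding_mV = holding_mV, inter_step_ms = inter_step_ms)
}

#' Standard h-current activation protocol
#'
#' Holding -50 mV; a series of 4 s hyperpolarizing steps from -60 to
#' -120 mV in 10 mV increments, 6 s between steps.
#'
#' @return A [step_protocol()] with 7 steps.
#' @export
ih_protocol <- function() {
  step_protocol(
    tibble(prepulse_mV = NA_real_, prepulse_ms = 0,
           test_mV = seq(-60, -120, by = -10), test_ms = 4000),
    holding_mV = -50, inter_step_ms = 6000)
}

#' A-current test and leak protocols
#'
#' Peak A-current protocol: from -50 mV holding, a 200 ms prepulse to
#' -90 mV removes resting inactivation, immediately followed by a 400 ms
#' activation step to +60 mV. For the matching leak protocol the prepulse
#' is set to -40 mV instead, which leaves the A-current inactivated so the
#' test step records leak (plus any non-A currents) only.
#'
#' @param deinactivating `TRUE` for the -90 mV (test) prepulse, `FALSE` for
#'   the -40 mV (leak) prepulse.
#' @return A single-step [step_protocol()].
#' @export
ia_protocol <- function(deinactivating = TRUE) {
  check_flag(deinactivating, "deinactivating")
  step_protocol(
    tibble(prepulse_mV = if (deinactivating) -90 else -40, prepulse_ms = 200,
           test_mV = 60, test_ms = 400),
    holding_mV = -50, inter_step_ms = 6000)
}

trace_step_window <- function(trace) {
  m <- trace_meta(trace)
  if (is.null(m$test_onset_ms)) {
    abort("trace carries no step metadata; pass `step_window` explicitly.")
  }
  c(onset = m$test_onset_ms, offset = m$test_offset_ms)
}

#' Measure the steady-state h-current of one hyperpolarizing step
#'
#' Two methods. `"exp_fit"` (the primary one) fits a single exponential
#' `I(t) = I0 + A * (1 - exp(-(t - t_onset) / tau))` over the step, skipping
#' the first `skip_ms` after the step onset (capacitive transient), and
#' back-extrapolates to the step onset: `A` is the slowly developing
#' steady-state h-current with the instantaneous leak jump `I0` excluded.
#' `"peak_minus_leak"` is the fallback for traces the fit cannot handle
#' (e.g. residual oscillations): the mean over the final 10% of the step
#' minus the initial fast leak current (mean over 2-10 ms post-onset).
#' Signs are preserved: an inward current is negative.
#'
#' @param trace A current [sampled_trace()] carrying step metadata (from
#'   [generate_clamp_trace()]), or any current trace if `step_window` given.
#' @param method `"exp_fit"` or `"peak_minus_leak"`.
#' @param step_window Optional `c(onset, offset)` in ms overriding metadata.
#' @param skip_ms Initial window excluded from the exponential fit, ms.
#' @param rmse_max_nA Optional ceiling on the fit RMSE; a noisier fit errors
#'   with a recommendation to use `"peak_minus_leak"`.
#' @return One-row tibble: `steady_state_nA`, `tau_ms`, `offset_nA`,
#'   `rmse_nA`, `method`, `test_mV` (tau/offset are `NA` for the
#'   subtraction method).
#' @export
measure_ih_peak <- function(trace, method = c("exp_fit", "peak_minus_leak"),
                            step_window = NULL, skip_ms = 5,
                            rmse_max_nA = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(trace, "sampled_trace"),
            identical(attr(trace, "kind"), "current"))
  win <- step_window %||% trace_step_window(trace)
  t <- trace$time_ms
  i <- trace_values(trace)
  on <- unname(win[1]); off <- unname(win[2])
  if (on < t[1] - 1e-9 || off > t[length(t)] + trace_dt(trace) + 1e-9) {
    abort("step window lies outside the trace.")
  }
  test_mV <- trace_meta(trace, "test_mV") %||% NA_real_

  if (method == "peak_minus_leak") {
    late <- i[t >= off - 0.1 * (off - on) & t < off]
    early <- i[t >= on + 2 & t <= on + 10]
    if (!length(late) || !length(early)) abort("step too short for the subtraction windows.")
    return(tibble(steady_state_nA = mean(late) - mean(early),
                  tau_ms = NA_real_, offset_nA = mean(early),
                  rmse_nA = NA_real_, method = method, test_mV = test_mV))
  }

  sel <- t >= on + skip_ms & t < off
  tt <- t[sel] - on
  ii <- i[sel]
  if (length(tt) < 10L) abort("too few samples in the step window for a fit.")
  # initial guesses: early/late plateaus and the 63% crossing time
  i0 <- mean(ii[seq_len(max(3L, round(0.02 * length(ii))))])
  iend <- mean(ii[tt >= max(tt) * 0.9])
  a0 <- iend - i0
  if (abs(a0) < .Machine$double.eps) a0 <- sign(iend - i0 + 1e-12) * 1e-6
  frac <- (ii - i0) / a0
  t63 <- suppressWarnings(tt[which(frac >= 0.632)[1]])
  tau0 <- if (is.na(t63) || t63 <= 0) max(tt) / 3 else t63
  fit <- tryCatch(
    minpack.lm::nlsLM(ii ~ I0 + A * (1 - exp(-tt / tau)),
                      start = list(I0 = i0, A = a0, tau = tau0),
                      lower = c(-Inf, -Inf, trace_dt(trace)),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) {
      abort(paste0("exponential fit failed (", conditionMessage(e),
                   "); consider method = \"peak_minus_leak\"."))
    })
  cf <- stats::coef(fit)
  rmse <- sqrt(mean(stats::resid(fit)^2))
  if (!is.null(rmse_max_nA) && rmse > rmse_max_nA) {
    abort(sprintf(paste0("fit rmse %.3g nA exceeds rmse_max_nA = %.3g; the trace ",
                         "may be interrupted - use method = \"peak_minus_leak\"."),
                  rmse, rmse_max_nA))
  }
  tibble(steady_state_nA = unname(cf["A"]), tau_ms = unname(cf["tau"]),
         offset_nA = unname(cf["I0"]), rmse_nA = rmse,
         method = method, test_mV = test_mV)
}

#' Measure a full h-current activation sweep
#'
#' Applies [measure_ih_peak()] to each trace of a protocol sweep and
#' converts the steady-state currents to conductances.
#'
#' @param traces List of current traces, one per step (see
#'   [generate_clamp_trace()]).
#' @param v_rev_mV Reversal potential used for the conductance conversion.
#' @inheritParams measure_ih_peak
#' @return Tibble with one row per step: the [measure_ih_peak()] columns
#'   plus `g_uS`.
#' @export
measure_ih_sweep <- function(traces, method = "exp_fit", v_rev_mV = -35,
                             skip_ms = 5) {
  purrr::map(traces, measure_ih_peak, method = method, skip_ms = skip_ms) |>
    dplyr::bind_rows() |>
    dplyr::mutate(g_uS = to_conductance(.data$steady_state_nA,
                                        .data$test_mV, v_rev_mV))
}

#' Peak A-current by prepulse leak subtraction
#'
#' Subtracts the leak-protocol trace (prepulse -40 mV: A-current stays
#' inactivated) from the test-protocol trace (prepulse -90 mV: resting
#' inactivation removed) sample-by-sample and returns the maximum of the
#' difference current during the +60 mV activation step. Outward currents
#' are positive.
#'
#' @param test_trace,leak_trace Current traces from the deinactivating and
#'   leak variants of [ia_protocol()], aligned on the same time grid.
#' @return Peak difference current, nA.
#' @export
measure_ia_peak <- function(test_trace, leak_trace) {
  stopifnot(inherits(test_trace, "sampled_trace"),
            inherits(leak_trace, "sampled_trace"))
  if (nrow(test_trace) != nrow(leak_trace)) {
    abort("test and leak traces differ in length; protocols must match.")
  }
  win <- trace_step_window(test_trace)
  t <- test_trace$time_ms
  d <- trace_values(test_trace) - trace_values(leak_trace)
  sel <- t >= win[1] & t < win[2]
  if (!any(sel)) abort("no samples inside the activation step.")
  max(d[sel])
}

#' Convert a peak current to a chord conductance
#'
#' `G = I_peak / (V_m - V_rev)`, uS from nA and mV.
#'
#' @param i_peak_nA Peak current(s), nA.
#' @param v_mV Step potential(s), mV.
#' @param v_rev_mV Reversal potential, mV.
#' @return Conductance(s), uS.
#' @examples
#' to_conductance(-8.5, -120, -35) # 0.1
#' @export
to_conductance <- function(i_peak_nA, v_mV, v_rev_mV) {
  if (any(abs(v_mV - v_rev_mV) < 1e-9)) {
    abort("`v_mV` equals `v_rev_mV`; the chord conductance is undefined.")
  }
  i_peak_nA / (v_mV - v_rev_mV)
}

#' Fit a first-order Boltzmann activation curve
#'
#' Least-squares fit of `G(V) = gmax / (1 + exp((V - v_half) / v_slope))`.
#' Sign convention: conductances activated by hyperpolarization (the
#' h-current) fit with a positive `v_slope`; activation by depolarization
#' gives a negative slope. Initial guesses: `gmax = max(G)`, `v_half` at the
#' half-maximum voltage, `v_slope = 8` with the sign inferred from the data
#' trend.
#'
#' @param data Data frame of the activation curve.
#' @param voltage,conductance <tidy-select> Columns holding step voltage
#'   (mV) and conductance (uS); defaults `test_mV` and `g_uS`, matching
#'   [measure_ih_sweep()] output.
#' @return An object of class `boltzmann_fit` with elements `gmax_uS`,
#'   `v_half_mV`, `v_slope_mV`, `rmse_uS`, `data`, `fit`. Has [tidy()],
#'   [glance()], `predict()` and `autoplot()` methods.
#' @export
fit_boltzmann <- function(data, voltage = test_mV, conductance = g_uS) {
  v <- dplyr::pull(data, {{ voltage }})
  g <- dplyr::pull(data, {{ conductance }})
  if (length(v) < 4L) abort("need at least 4 points spanning the transition.")
  gmax0 <- max(abs(g))
  vh0 <- v[which.min(abs(abs(g) - gmax0 / 2))]
  # rising G with hyperpolarization -> positive slope
  slope_sign <- if (stats::cor(v, g) < 0) 1 else -1
  start <- list(gmax = gmax0, v_half = vh0, v_slope = slope_sign * 8)
  fit <- tryCatch(
    minpack.lm::nlsLM(g ~ gmax / (1 + exp((v - v_half) / v_slope)),
                      start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) {
      abort(sprintf(paste0("Boltzmann fit did not converge (%s); initial ",
                           "guesses were gmax = %.3g, v_half = %.3g, ",
                           "v_slope = %.3g."),
                    conditionMessage(e), start$gmax, start$v_half, start$v_slope))
    })
  cf <- stats::coef(fit)
  structure(list(gmax_uS = unname(cf["gmax"]),
                 v_half_mV = unname(cf["v_half"]),
                 v_slope_mV = unname(cf["v_slope"]),
                 rmse_uS = sqrt(mean(stats::resid(fit)^2)),
                 data = tibble(v_mV = v, g_uS = g),
                 fit = fit),
            class = "boltzmann_fit")
}

#' @export
print.boltzmann_fit <- function(x, ...) {
  cat(sprintf(paste0("<boltzmann_fit> gmax = %.4g uS, v_half = %.4g mV, ",
                     "v_slope = %.4g mV (rmse %.3g uS)\n"),
              x$gmax_uS, x$v_half_mV, x$v_slope_mV, x$rmse_uS))
  invisible(x)
}

#' @export
predict.boltzmann_fit <- function(object, v_mV, ...) {
  object$gmax_uS / (1 + exp((v_mV - object$v_half_mV) / object$v_slope_mV))
}
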