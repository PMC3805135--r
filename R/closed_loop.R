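#' Configuration of a voltage-clamp metaplasticity experiment
#'
#' Describes the in-silico analogue of the recurring-step clamp
#' experiments: a baseline command mimicking pre-dopamine slow-wave
#' activity, the dopamine-condition command (shortened step, optionally
#' faster cycle, optional spike mimicry), the channel models measured, and
#' the measurement schedule. The activity index driving the plasticity rule
#' is read off the two commands: percent change in step (burst) duration,
#' percent change in cycle frequency, and the spike mode of the
#' dopamine-condition command.
#'
#' @param command Dopamine-condition [command_waveform()].
#' @param baseline_command Pre-dopamine [command_waveform()].
#' @param da_mode `"micromolar"`, `"nanomolar"` or `"none"`.
#' @param duration_min Experiment duration, minutes.
#' @param measure_times_min Times (minutes) at which the currents are
#'   re-measured with the in-silico clamp pipeline; must start at 0 and lie
#'   within `duration_min`.
#' @param ia_da_factor Immediate modulatory fold applied to the A-current
#'   maximal conductance at dopamine onset.
#' @param ih,ia Channel models at baseline ([h_channel()], [a_channel()]).
#' @param leak Ohmic leak, `list(g_uS =, e_mV =)`.
#' @param curve Activity-dependence rule; defaults to
#'   `calibrate_ad_curve(da_mode)`.
#' @param noise_sd_nA Measurement noise SD, nA.
#' @param seed Integer seed for measurement noise.
#' @return An object of class `clamp_experiment_config`.
#' @export
clamp_experiment_config <- function(command,
                                    baseline_command = command_waveform(),
                                    da_mode = c("micromolar", "nanomolar", "none"),
                                    duration_min = 10,
                                    measure_times_min = c(0, duration_min),
                                    ia_da_factor = 0.81,
                                    ih = h_channel(g_max_uS = 0.1),
                                    ia = a_channel(g_max_uS = 0.6),
                                    leak = list(g_uS = 0.05, e_mV = -50),
                                    curve = NULL,
                                    noise_sd_nA = 0.05,
                                    seed = 1L) {
  da_mode <- match.arg(da_mode)
  stopifnot(inherits(command, "command_waveform"),
            inherits(baseline_command, "command_waveform"),
            inherits(ih, "h_channel"), inherits(ia, "a_channel"))
  check_positive(duration_min, "duration_min")
  check_positive(ia_da_factor, "ia_da_factor")
  if (any(measure_times_min < 0 | measure_times_min > duration_min)) {
    abort("`measure_times_min` must lie within [0, duration_min].")
  }
  if (measure_times_min[1] != 0) abort("`measure_times_min` must start at 0.")
  curve <- curve %||% calibrate_ad_curve(da_mode)
  structure(list(command = command, baseline_command = baseline_command,
                 da_mode = da_mode, duration_min = duration_min,
                 measure_times_min = sort(unique(measure_times_min)),
                 ia_da_factor = ia_da_factor, ih = ih, ia = ia, leak = leak,
                 curve = curve, noise_sd_nA = noise_sd_nA, seed = seed),
            class = "clamp_experiment_config")
}

# activity index implied by a pair of commands
command_activity_index <- function(command, baseline) {
  list(delta_burst_pct = 100 * (command$step_ms - baseline$step_ms) / baseline$step_ms,
       delta_freq_pct = 100 * (baseline$cycle_period_ms / command$cycle_period_ms - 1),
       spike_mode = command$spike_mode)
}

# One full in-silico measurement of both currents at given conductances.
measure_both_currents <- function(g_h, g_a, cfg, seed) {
  ih_ch <- cfg$ih; ih_ch$g_max_uS <- g_h
  ia_ch <- cfg$ia; ia_ch$g_max_uS <- g_a
  sweep <- generate_clamp_trace(list(ih_ch), cfg$leak, ih_protocol(),
                                noise_sd_nA = cfg$noise_sd_nA,
                                seed = substream_seed(seed, "ih")) |>
    measure_ih_sweep(v_rev_mV = cfg$ih$e_rev_mV)
  bfit <- fit_boltzmann(sweep)
  test <- generate_clamp_trace(list(ia_ch), cfg$leak, ia_protocol(TRUE),
                               noise_sd_nA = cfg$noise_sd_nA,
                               seed = substream_seed(seed, "ia_test"),
                               dt_ms = 0.1)[[1]]
  lk <- generate_clamp_trace(list(ia_ch), cfg$leak, ia_protocol(FALSE),
                             noise_sd_nA = cfg$noise_sd_nA,
                             seed = substream_seed(seed, "ia_leak"),
                             dt_ms = 0.1)[[1]]
  list(ih_gmax_uS = bfit$gmax_uS,
       ih_peak_nA = sweep$steady_state_nA[sweep$test_mV == -120],
       ia_peak_nA = measure_ia_peak(test, lk))
}

#' Run a closed-loop clamp-experiment emulation
#'
#' Reproduces the recurring-voltage-step experiments end to end: at t = 0
#' both currents are measured with the in-silico clamp pipeline
#' (exponential-fit h-current sweep with Boltzmann `G_max`, prepulse
#' leak-subtracted peak A-current). Dopamine arrives immediately after:
#' the A-current conductance drops by `ia_da_factor`, and the
#' activity-dependence rule starts relaxing the h-current `G_max` toward
#' `target_fold * G_max0` with time constant `tau_ad_min`, driven by the
#' activity index implied by the dopamine-condition command. Both currents
#' are re-measured at each requested time.
#'
#' @param config A [clamp_experiment_config()].
#' @return An `experiment_result` tibble: one row per measurement time with
#'   raw measures (`ih_gmax_uS`, `ih_peak_nA`, `ia_peak_nA`) and
#'   fold-changes relative to t = 0 (`ih_gmax_fold`, `ih_peak_fold`,
#'   `ia_fold`, `ratio_fold` = A-to-h peak-ratio fold).
#' @export
run_clamp_experiment <- function(config) {
  stopifnot(inherits(config, "clamp_experiment_config"))
  idx <- command_activity_index(config$command, config$baseline_command)
  fold <- target_fold(config$curve, idx$delta_burst_pct, idx$delta_freq_pct,
                      idx$spike_mode)
  tau_eff <- config$curve$tau_ad_min *
    if (identical(idx$spike_mode, "patterned")) config$curve$patterned_tau_multiplier else 1
  g_h0 <- config$ih$g_max_uS
  g_a0 <- config$ia$g_max_uS

  rows <- purrr::map(config$measure_times_min, function(tm) {
    if (tm == 0) {
      g_h <- g_h0; g_a <- g_a0
    } else {
      g_h <- g_h0 * (fold + (1 - fold) * exp(-tm / tau_eff))
      g_a <- g_a0 * config$ia_da_factor
    }
    m <- tryCatch(
      measure_both_currents(g_h, g_a, config,
                            seed = substream_seed(config$seed, paste0("t", tm))),
      error = function(e) abort(sprintf("measurement at t = %g min failed: %s",
                                        tm, conditionMessage(e))))
    tibble(time_min = tm, ih_gmax_uS = m$ih_gmax_uS,
           ih_peak_nA = m$ih_peak_nA, ia_peak_nA = m$ia_peak_nA)
  })
  out <- dplyr::bind_rows(rows) |>
    dplyr::mutate(ih_gmax_fold = .data$ih_gmax_uS / .data$ih_gmax_uS[1],
                  ih_peak_fold = .data$ih_peak_nA / .data$ih_peak_nA[1],
                  ia_fold = .data$ia_peak_nA / .data$ia_peak_nA[1],
                  ratio_fold = .data$ia_fold / .data$ih_peak_fold)
  structure(out, class = c("experiment_result", class(out)),
            config = config, target_fold = fold,
            activity_index = idx)
}

#' Predicted metaplastic fold-change used for dynamic-clamp subtraction
#'
#' Pure lookup of the activity-dependence curve at a measured
#' burst-duration change (no frequency term, no spike gating) - the
#' quantity incorporated into the dynamic-clamp model to cancel the
#' plastic change.
#'
#' @param curve An [calibrate_ad_curve()] object.
#' @param delta_burst_pct Measured percent change in burst duration.
#' @return Predicted fold.
#' @examples
#' predict_metaplastic_fold(calibrate_ad_curve(), -30) # 0.94
#' @export
predict_metaplastic_fold <- function(curve, delta_burst_pct) {
  target_fold(curve, delta_burst_pct, delta_freq_pct = 0, spike_mode = "none")
}
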