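#' Configuration of the minimal rebound-neuron network experiment
#'
#' A single-compartment follower neuron (leak + transient A-current + slow
#' h-current) is rhythmically inhibited by a pacemaker modelled as a timing
#' source: each cycle starts with a square synaptic-inhibition pulse
#' (`inhibition_duty` of the period), and the end of the pulse stands for
#' the last pacemaker spike. Post-inhibitory rebound follows; spiking is a
#' threshold proxy (burst onset = first suprathreshold crossing, burst
#' duration = suprathreshold time until the next inhibition). A dopamine
#' event scales the A-current conductance immediately and the pacemaker
#' period, and switches on the activity-dependent regulation of the
#' h-current `G_max`; optionally a dynamic-clamp add-back current cancels
#' the predicted metaplastic change.
#'
#' Default membrane and channel parameters were tuned (tools/tune_network.R)
#' so that the baseline rebound latency sits well inside the release window
#' at a 1 s period, latencies stay finite and monotone over a +/-30%
#' conductance grid, and the dopamine condition (A-current conductance
#' times 0.81, period times 0.90) advances the firing phase by roughly 20%.
#'
#' @param c_nF Membrane capacitance, nF.
#' @param g_leak_uS,e_leak_mV Ohmic leak.
#' @param ih,ia Channel models ([h_channel()], [a_channel()]); the network
#'   cell uses subthreshold-shifted A-current activation.
#' @param g_syn_uS,e_syn_mV Inhibitory synapse conductance and reversal.
#' @param inhibition_duty Fraction of each cycle spent inhibited.
#' @param pacemaker_period_ms Baseline cycle period, ms.
#' @param spike_threshold_mV Threshold-crossing proxy for spiking; must be
#'   above `e_leak_mV`.
#' @param da_onset_min Dopamine arrival time, minutes.
#' @param ia_factor,period_factor Immediate dopamine effects (A-current
#'   conductance fold, pacemaker period fold).
#' @param curve Activity-dependence rule for the h-current.
#' @param spike_mode How the neuron's own spiking enters the plasticity
#'   rule. The rebound neuron fires patterned spikes during its bursts, so
#'   the default `"patterned"` runs the G_max relaxation with the slowed
#'   (patterned-spike) time constant, reproducing the slow phase recovery
#'   seen in intact preparations; `"none"` uses the fast slow-wave-only
#'   kinetics.
#' @param addback Engage the dynamic-clamp add-back current
#'   (`(1 - G_max fold) * G_max0 * m * (V - E_rev)`), which continuously
#'   cancels the metaplastic change from
#'   `da_onset_min + addback_delay_min` onward.
#' @param addback_delay_min Delay before the add-back engages, minutes.
#' @param dt_ms Integration step, ms.
#' @return An object of class `rebound_neuron_config`.
#' @export
rebound_neuron_config <- function(c_nF = 5,
                                  g_leak_uS = 0.05, e_leak_mV = -55,
                                  ih = h_channel(g_max_uS = 0.8,
                                                 v_half_mV = -85, v_slope_mV = 7,
                                                 tau_max_ms = 1500,
                                                 tau_v_half_mV = -85,
                                                 tau_v_slope_mV = 30),
                                  ia = a_channel(g_max_uS = 1.0,
                                                 act_v_half_mV = -50,
                                                 act_v_slope_mV = -4,
                                                 act_tau_ms = 3,
                                                 inact_v_half_mV = -60,
                                                 inact_v_slope_mV = 4,
                                                 inact_tau_ms = 120),
                                  g_syn_uS = 0.5, e_syn_mV = -80,
                                  inhibition_duty = 0.4,
                                  pacemaker_period_ms = 1000,
                                  spike_threshold_mV = -52,
                                  da_onset_min = 0,
                                  ia_factor = 0.81, period_factor = 0.90,
                                  curve = calibrate_ad_curve("micromolar"),
                                  spike_mode = c("patterned", "none"),
                                  addback = FALSE, addback_delay_min = 10,
                                  dt_ms = 0.05) {
  spike_mode <- match.arg(spike_mode)
  check_positive(c_nF, "c_nF")
  check_positive(g_syn_uS, "g_syn_uS")
  check_positive(pacemaker_period_ms, "pacemaker_period_ms")
  check_number(inhibition_duty, "inhibition_duty", lower = 0.05, upper = 0.9)
  if (spike_threshold_mV <= e_leak_mV) {
    abort("`spike_threshold_mV` must be above `e_leak_mV`.")
  }
  check_flag(addback, "addback")
  check_positive(dt_ms, "dt_ms")
  stopifnot(inherits(ih, "h_channel"), inherits(ia, "a_channel"),
            inherits(curve, "ad_curve"))
  structure(list(c_nF = c_nF, g_leak_uS = g_leak_uS, e_leak_mV = e_leak_mV,
                 ih = ih, ia = ia, g_syn_uS = g_syn_uS, e_syn_mV = e_syn_mV,
                 inhibition_duty = inhibition_duty,
                 pacemaker_period_ms = pacemaker_period_ms,
                 spike_threshold_mV = spike_threshold_mV,
                 da_onset_min = da_onset_min, ia_factor = ia_factor,
                 period_factor = period_factor, curve = curve,
                 spike_mode = spike_mode,
                 addback = addback, addback_delay_min = addback_delay_min,
                 dt_ms = dt_ms),
            class = "rebound_neuron_config")
}

# Simulate n cycles at fixed conductances; returns per-cycle latency and
# suprathreshold burst duration after settle_cycles discarded.
simulate_rebound_cycles <- function(cfg, g_a, g_h, period_ms,
                                    n_cycles = 3, settle_cycles = 2,
                                    g_h_addback = 0, return_trace = FALSE) {
  dt <- cfg$dt_ms
  total <- (settle_cycles + n_cycles) * period_ms
  n <- as.integer(round(total / dt))
  t <- (seq_len(n) - 1L) * dt
  inh_ms <- cfg$inhibition_duty * period_ms
  g_syn_t <- ifelse(t %% period_ms < inh_ms, cfg$g_syn_uS, 0)
  v0 <- -65
  st_a <- channel_steady_state(cfg$ia, v0)
  st_h <- channel_steady_state(cfg$ih, v0)
  sim <- rebound_sim_cpp(
    g_syn_t, dt, cfg$c_nF, cfg$g_leak_uS, cfg$e_leak_mV, cfg$e_syn_mV,
    g_a, cfg$ia$e_rev_mV,
    cfg$ia$act_v_half_mV, cfg$ia$act_v_slope_mV, cfg$ia$act_tau_ms,
    cfg$ia$act_exponent,
    cfg$ia$inact_v_half_mV, cfg$ia$inact_v_slope_mV, cfg$ia$inact_tau_ms,
    g_h + g_h_addback, cfg$ih$e_rev_mV,
    cfg$ih$v_half_mV, cfg$ih$v_slope_mV, cfg$ih$tau_max_ms,
    cfg$ih$tau_v_half_mV, cfg$ih$tau_v_slope_mV,
    v0, st_a$m, st_a$h, st_h$m)
  v <- sim$v
  above <- v >= cfg$spike_threshold_mV
  cyc <- purrr::map(seq_len(n_cycles), function(i) {
    k <- settle_cycles + i - 1L
    rel <- k * period_ms + inh_ms
    nxt <- (k + 1L) * period_ms
    sel <- which(t >= rel & t < nxt)
    hit <- sel[above[sel]]
    if (length(hit) == 0L) {
      return(tibble(cycle = i, latency_ms = NA_real_, burst_ms = 0))
    }
    tibble(cycle = i, latency_ms = t[hit[1L]] - rel,
           burst_ms = length(hit) * dt)
  }) |> dplyr::bind_rows()
  if (return_trace) {
    list(cycles = cyc, trace = sampled_trace(t, v, kind = "voltage", dt_ms = dt))
  } else {
    cyc
  }
}

#' Post-inhibitory rebound latency for a given conductance pair
#'
#' Entrains the rebound neuron to the pacemaker for a few cycles, then
#' measures the time from the end of an inhibitory pulse to the first
#' threshold crossing. The latency increases with the A-current conductance
#' and decreases with the h-current conductance; scaling both by the same
#' fold leaves it nearly unchanged (ratio invariance).
#'
#' @param g_a_uS,g_h_uS Maximal conductances, uS.
#' @param config A [rebound_neuron_config()].
#' @return Latency, ms.
#' @export
rebound_latency <- function(g_a_uS, g_h_uS, config = rebound_neuron_config()) {
  check_number(g_a_uS, "g_a_uS", lower = 0)
  check_number(g_h_uS, "g_h_uS", lower = 0)
  cyc <- simulate_rebound_cycles(config, g_a_uS, g_h_uS,
                                 config$pacemaker_period_ms,
                                 n_cycles = 1, settle_cycles = 3)
  if (is.na(cyc$latency_ms[1])) {
    abort(sprintf(paste0("no threshold crossing within one period ",
                         "(g_a = %g uS, g_h = %g uS, threshold %g mV): ",
                         "the neuron is silent; increase g_h or lower the ",
                         "threshold."), g_a_uS, g_h_uS, config$spike_threshold_mV))
  }
  cyc$latency_ms[1]
}

#' Run the closed-loop network experiment
#'
#' Simulates the rebound neuron through a dopamine application. Before
#' dopamine the baseline latency, burst duration and phase are recorded.
#' At `da_onset_min` the A-current conductance drops by `ia_factor` and the
#' pacemaker period by `period_factor` (the immediate modulatory arm), and
#' the dopamine-enabled rule starts relaxing the h-current `G_max` toward
#' the target set by the realized burst-duration and cycle-frequency
#' changes (the activity-dependent arm). Channel dynamics run at `dt_ms`;
#' the plasticity state updates every `update_min` using burst metrics
#' averaged over `measure_cycles` cycles. With `addback = TRUE` a
#' dynamic-clamp current reintroduces the predicted lost conductance from
#' `da_onset_min + addback_delay_min` onward, abrogating the plastic arm.
#'
#' @param config A [rebound_neuron_config()].
#' @param duration_min Simulated time, minutes.
#' @param update_min Plasticity update interval, minutes.
#' @param measure_cycles Cycles averaged per metric sample.
#' @return An `experiment_result` tibble: `time_min`, `latency_ms`,
#'   `burst_ms`, `period_ms`, `lp_on_phase`, `gh_fold`, `ga_fold`, and
#'   fold-changes `phase_fold`, `burst_fold` relative to t = 0.
#' @export
run_network_experiment <- function(config, duration_min = 30,
                                   update_min = 0.5, measure_cycles = 3) {
  stopifnot(inherits(config, "rebound_neuron_config"))
  check_positive(duration_min, "duration_min")
  check_positive(update_min, "update_min")
  g_a0 <- config$ia$g_max_uS
  g_h0 <- config$ih$g_max_uS
  period0 <- config$pacemaker_period_ms

  base <- simulate_rebound_cycles(config, g_a0, g_h0, period0,
                                  n_cycles = measure_cycles)
  if (anyNA(base$latency_ms)) {
    abort("baseline neuron is silent (no rebound crossing); retune the config.")
  }
  lat0 <- mean(base$latency_ms); burst0 <- mean(base$burst_ms)
  state <- metaplastic_state(g_h0)

  times <- seq(0, duration_min, by = update_min)
  rows <- vector("list", length(times))
  for (k in seq_along(times)) {
    tm <- times[k]
    da_on <- tm > config$da_onset_min ||
      (config$da_onset_min == 0 && tm > 0)
    g_a <- if (da_on) g_a0 * config$ia_factor else g_a0
    period <- if (da_on) period0 * config$period_factor else period0
    # add-back current (1 - fold) * g0 * m * (V - E_rev): same gating as the
    # h-current, so it folds into an extra conductance that continuously
    # cancels the metaplastic change once engaged
    addback_g <- if (config$addback && da_on &&
                     tm >= config$da_onset_min + config$addback_delay_min) {
      g_h0 - state$g_uS
    } else {
      0
    }
    cyc <- simulate_rebound_cycles(config, g_a, state$g_uS, period,
                                   n_cycles = measure_cycles,
                                   g_h_addback = addback_g)
    if (anyNA(cyc$latency_ms)) {
      abort(sprintf("neuron fell silent at t = %g min (g_a = %g, g_h = %g uS).",
                    tm, g_a, state$g_uS))
    }
    lat <- mean(cyc$latency_ms); burst <- mean(cyc$burst_ms)
    rows[[k]] <- tibble(time_min = tm, latency_ms = lat, burst_ms = burst,
                        period_ms = period, lp_on_phase = lat / period,
                        gh_fold = state$g_uS / g_h0,
                        ga_fold = g_a / g_a0)
    if (da_on) {
      state <- advance_gmax(state, config$curve,
                            delta_burst_pct = 100 * (burst - burst0) / burst0,
                            delta_freq_pct = 100 * (period0 / period - 1),
                            spike_mode = config$spike_mode,
                            dt_min = update_min)
    }
  }
  out <- dplyr::bind_rows(rows) |>
    dplyr::mutate(phase_fold = .data$lp_on_phase / .data$lp_on_phase[1],
                  burst_fold = .data$burst_ms / .data$burst_ms[1])
  structure(out, class = c("experiment_result", class(out)),
            config = config, baseline = list(latency_ms = lat0,
                                             burst_ms = burst0,
                                             period_ms = period0))
}
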