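#' Generate a paired pacemaker/follower spike recording
#'
#' Builds PD and LP spike trains directly as spike times (no membrane
#' simulation): cycle i anchors its last PD spike at `i * cycle_period_ms`,
#' the PD burst ends there, and the LP burst begins `lp_on_delay_ms` later
#' and spans `lp_burst_ms`. LP spikes span the full burst window; the number
#' of within-burst intervals per cycle follows a deterministic accumulator on
#' `lp_burst_ms / lp_mean_isi_ms` so the long-run mean ISI equals the preset
#' even when that ratio is not an integer. Independent Gaussian jitter is
#' applied to cycle anchors (`cycle_jitter_sd_ms`) and to every spike
#' (`spike_jitter_sd_ms`), then order is restored within bursts.
#'
#' With both jitter SDs at zero the output is an exact deterministic function
#' of the preset (same seed or not), and realized metrics equal the preset
#' parameters exactly.
#'
#' @param preset A [network_preset()].
#' @param duration_ms Recording length, ms; must cover at least 10 cycles.
#' @param seed Integer seed for the jitter draws.
#' @return A tibble of class `spike_recording` with columns `cell_id`
#'   (`"PD"`/`"LP"`) and `spike_time_ms`, carrying the realized per-burst
#'   windows in `attr(, "burst_windows")`.
#' @examples
#' rec <- generate_network_recording(network_preset(), 20000, seed = 1)
#' dplyr::count(rec, cell_id)
#' @export
generate_network_recording <- function(preset, duration_ms, seed = 1L) {
  stopifnot(inherits(preset, "network_preset"))
  check_positive(duration_ms, "duration_ms")
  if (duration_ms < 10 * preset$cycle_period_ms) {
    abort("`duration_ms` must cover at least 10 cycles of `cycle_period_ms`.")
  }
  p <- preset
  n_cycles <- floor(duration_ms / p$cycle_period_ms)
  jitter_on <- p$cycle_jitter_sd_ms > 0 || p$spike_jitter_sd_ms > 0

  build <- function() {
    anchors <- seq_len(n_cycles) * p$cycle_period_ms
    if (p$cycle_jitter_sd_ms > 0) {
      anchors <- anchors + stats::rnorm(n_cycles, 0, p$cycle_jitter_sd_ms)
    }

    # PD burst: spikes end at the anchor; internal spacing ~25 ms.
    k_pd <- max(1L, as.integer(round(p$pd_burst_ms / 25)))
    pd <- purrr::map(anchors, function(a) {
      seq(a - p$pd_burst_ms, a, length.out = k_pd + 1L)
    })

    # LP burst: spans [anchor + delay, anchor + delay + burst]; interval
    # count per burst by error accumulation on burst/ISI so the realized
    # mean ISI matches the preset.
    q <- p$lp_burst_ms / p$lp_mean_isi_ms
    err <- 0
    lp <- vector("list", n_cycles)
    for (i in seq_len(n_cycles)) {
      onset <- anchors[i] + p$lp_on_delay_ms
      offset <- onset + p$lp_burst_ms
      if (offset > duration_ms + p$cycle_jitter_sd_ms * 4) break
      k <- max(1L, as.integer(floor(q + err + 1e-9)))
      err <- q + err - k
      lp[[i]] <- seq(onset, offset, length.out = k + 1L)
    }
    lp <- purrr::compact(lp)

    jitter_burst <- function(spk) {
      if (p$spike_jitter_sd_ms > 0) {
        spk <- sort(spk + stats::rnorm(length(spk), 0, p$spike_jitter_sd_ms))
      }
      spk
    }
    pd <- purrr::map(pd, jitter_burst)
    lp <- purrr::map(lp, jitter_burst)
    list(pd = pd, lp = lp)
  }
  bursts <- if (jitter_on) with_seed(seed, build()) else build()

  windows <- function(lst, cell) {
    tibble(cell_id = cell, cycle = seq_along(lst),
           onset_ms = purrr::map_dbl(lst, 1),
           offset_ms = purrr::map_dbl(lst, ~ .x[length(.x)]),
           n_spikes = lengths(lst))
  }
  out <- dplyr::bind_rows(
    tibble(cell_id = "PD", spike_time_ms = unlist(bursts$pd)),
    tibble(cell_id = "LP", spike_time_ms = unlist(bursts$lp)))
  structure(out,
            class = c("spike_recording", class(out)),
            burst_windows = dplyr::bind_rows(windows(bursts$pd, "PD"),
                                             windows(bursts$lp, "LP")),
            preset = p, seed = seed)
}

#' Realized burst windows of a generated recording
#'
#' @param recording A `spike_recording` from [generate_network_recording()].
#' @return Tibble with one row per generated burst: `cell_id`, `cycle`,
#'   `onset_ms`, `offset_ms`, `n_spikes`.
#' @export
burst_windows <- function(recording) {
  attr(recording, "burst_windows")
}

#' Recurring voltage-step command waveform
#'
#' Describes the clamp command used to mimic slow-wave activity: each cycle
#' holds the nadir voltage and steps to the peak voltage for
#' `step_ms`. Optional spike mimicry superimposes depolarizations to
#' `spike_peak_mV` on the plateau: `"lumped"` inserts one step of width
#' `spike_count * spike_width_ms`; `"patterned"` inserts `spike_count`
#' depolarizations of `spike_width_ms` separated by gaps of `spike_isi_ms`.
#'
#' @param nadir_mV,peak_mV Slow-wave nadir and plateau voltages.
#' @param step_ms Plateau (mimicked burst) duration, ms.
#' @param cycle_period_ms Cycle period, ms.
#' @param spike_mode `"none"`, `"lumped"` or `"patterned"`.
#' @param spike_peak_mV Spike-mimic voltage (intra-axonal spike peak).
#' @param spike_width_ms Single spike width, ms.
#' @param spike_count Spikes per burst mimicked.
#' @param spike_isi_ms Gap between patterned depolarizations, ms.
#' @param n_cycles Number of cycles to render.
#' @return An object of class `command_waveform`.
#' @export
command_waveform <- function(nadir_mV = -60, peak_mV = -40, step_ms = 300,
                             cycle_period_ms = 1000,
                             spike_mode = c("none", "lumped", "patterned"),
                             spike_peak_mV = 40, spike_width_ms = 2,
                             spike_count = 6, spike_isi_ms = NULL,
                             n_cycles = 10) {
  spike_mode <- match.arg(spike_mode)
  check_number(nadir_mV, "nadir_mV")
  check_number(peak_mV, "peak_mV")
  if (nadir_mV >= peak_mV) abort("`nadir_mV` must be below `peak_mV`.")
  check_positive(step_ms, "step_ms")
  check_positive(cycle_period_ms, "cycle_period_ms")
  if (step_ms >= cycle_period_ms) abort("`step_ms` must be < `cycle_period_ms`.")
  check_number(n_cycles, "n_cycles", lower = 1)
  if (spike_mode != "none") {
    check_positive(spike_width_ms, "spike_width_ms")
    check_number(spike_count, "spike_count", lower = 1)
    if (spike_mode == "lumped" && spike_count * spike_width_ms > step_ms) {
      abort("lumped spike step does not fit within `step_ms`.")
    }
    if (spike_mode == "patterned") {
      check_number(spike_isi_ms, "spike_isi_ms", lower = 0)
      span <- spike_count * spike_width_ms + (spike_count - 1) * spike_isi_ms
      if (span > step_ms) {
        abort(sprintf(
          "patterned spikes span %g ms but `step_ms` is only %g ms.",
          span, step_ms))
      }
    }
  }
  structure(list(nadir_mV = nadir_mV, peak_mV = peak_mV, step_ms = step_ms,
                 cycle_period_ms = cycle_period_ms, spike_mode = spike_mode,
                 spike_peak_mV = spike_peak_mV, spike_width_ms = spike_width_ms,
                 spike_count = spike_count, spike_isi_ms = spike_isi_ms,
                 n_cycles = n_cycles),
            class = "command_waveform")
}

#' Render a command waveform as a sampled voltage trace
#'
#' @param waveform A [command_waveform()].
#' @param dt_ms Sampling interval, ms (default 0.05, i.e. 20 kHz).
#' @return A voltage [sampled_trace()].
#' @examples
#' cmd <- generate_command(command_waveform(n_cycles = 2), dt_ms = 1)
#' range(cmd$v_mV)
#' @export
generate_command <- function(waveform, dt_ms = 0.05) {
  stopifnot(inherits(waveform, "command_waveform"))
  check_positive(dt_ms, "dt_ms")
  w <- waveform
  n <- as.integer(round(w$n_cycles * w$cycle_period_ms / dt_ms))
  t <- (seq_len(n) - 1L) * dt_ms
  tc <- t %% w$cycle_period_ms
  v <- ifelse(tc < w$step_ms, w$peak_mV, w$nadir_mV)
  if (w$spike_mode == "lumped") {
    v[tc < w$spike_count * w$spike_width_ms] <- w$spike_peak_mV
  } else if (w$spike_mode == "patterned") {
    pitch <- w$spike_width_ms + w$spike_isi_ms
    within <- tc %% pitch
    idx <- tc < w$spike_count * pitch - w$spike_isi_ms & within < w$spike_width_ms
    v[idx] <- w$spike_peak_mV
  }
  sampled_trace(t, v, kind = "voltage", dt_ms = dt_ms,
                meta = list(waveform = unclass(w)))
}

#' Forward-simulate voltage-clamp current traces
#'
#' Generates the current a clamp amplifier would record for each step of a
#' protocol, from known channel models plus an ohmic leak, with optional
#' additive white Gaussian noise. Channel gates start at steady state for
#' the holding potential. One current trace is returned per protocol step;
#' each carries its step timing in the trace metadata so the measurement
#' functions can find their analysis windows.
#'
#' @param channels List of [h_channel()] / [a_channel()] objects (may be
#'   empty for a pure-leak trace).
#' @param leak List `list(g_uS =, e_mV =)` describing the ohmic leak.
#' @param protocol A [step_protocol()].
#' @param noise_sd_nA Per-sample noise SD, nA.
#' @param seed Integer seed for the noise.
#' @param dt_ms Sampling interval, ms.
#' @param pre_ms Holding time rendered before the first commanded step, ms.
#' @return List of current [sampled_trace()]s, one per protocol step.
#' @export
generate_clamp_trace <- function(channels, leak, protocol, noise_sd_nA = 0,
                                 seed = 1L, dt_ms = 0.5, pre_ms = 200) {
  stopifnot(inherits(protocol, "step_protocol"))
  if (inherits(channels, "channel")) channels <- list(channels)
  check_number(noise_sd_nA, "noise_sd_nA", lower = 0)
  check_positive(dt_ms, "dt_ms")
  holding <- attr(protocol, "holding_mV")
  steps <- as.data.frame(protocol)

  make_one <- function(row, step_idx) {
    seg_v <- c(holding, row$prepulse_mV, row$test_mV)
    seg_ms <- c(pre_ms, row$prepulse_ms, row$test_ms)
    keep <- !is.na(seg_v) & seg_ms > 0
    seg_v <- seg_v[keep]; seg_ms <- seg_ms[keep]
    n_seg <- as.integer(round(seg_ms / dt_ms))
    v <- rep(seg_v, n_seg)
    t <- (seq_along(v) - 1L) * dt_ms
    i <- leak$g_uS * (v - leak$e_mV)
    for (ch in channels) i <- i + channel_current_trace(ch, v, dt_ms)
    if (noise_sd_nA > 0) i <- i + stats::rnorm(length(i), 0, noise_sd_nA)
    onsets <- cumsum(c(0, seg_ms))
    sampled_trace(t, i, kind = "current", dt_ms = dt_ms,
                  meta = list(step = step_idx,
                              holding_mV = holding,
                              prepulse_mV = row$prepulse_mV,
                              prepulse_ms = row$prepulse_ms,
                              test_mV = row$test_mV,
                              test_ms = row$test_ms,
                              test_onset_ms = onsets[length(onsets) - 1L],
                              test_offset_ms = onsets[length(onsets)]))
  }
  with_seed(seed, {
    purrr::map(seq_len(nrow(steps)), function(k) make_one(steps[k, ], k))
  })
}
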