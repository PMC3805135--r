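#' Hyperpolarization-activated (h-type) conductance model
#'
#' The dynamic-clamp model of the inward h-current: a single first-order
#' Boltzmann gate `m` with voltage-dependent time constant, injecting
#' `I = g_max * m * (V - e_rev)` (uS * mV = nA). The reversal potential
#' defaults to -35 mV. The activation midpoint, slope and the bell-shaped
#' tau(V) defaults are stated assumptions (the source recordings do not pin
#' them); they place the current near steady state within a 4 s
#' hyperpolarizing step.
#'
#' @param g_max_uS Maximal conductance, uS.
#' @param e_rev_mV Reversal potential, mV.
#' @param v_half_mV Activation midpoint, mV.
#' @param v_slope_mV Activation slope, mV. Positive: activated by
#'   hyperpolarization.
#' @param tau_max_ms Peak of the activation time constant, ms.
#' @param tau_v_half_mV Voltage of the tau peak, mV.
#' @param tau_v_slope_mV Width of the tau bell, mV.
#' @return An object of class `h_channel`.
#' @export
h_channel <- function(g_max_uS, e_rev_mV = -35, v_half_mV = -95,
                      v_slope_mV = 8, tau_max_ms = 800,
                      tau_v_half_mV = -95, tau_v_slope_mV = 20) {
  check_number(g_max_uS, "g_max_uS", lower = 0)
  check_number(e_rev_mV, "e_rev_mV")
  check_number(v_half_mV, "v_half_mV")
  if (v_slope_mV == 0) abort("`v_slope_mV` must be nonzero.")
  check_positive(tau_max_ms, "tau_max_ms")
  check_positive(tau_v_slope_mV, "tau_v_slope_mV")
  structure(list(g_max_uS = g_max_uS, e_rev_mV = e_rev_mV,
                 v_half_mV = v_half_mV, v_slope_mV = v_slope_mV,
                 tau_max_ms = tau_max_ms, tau_v_half_mV = tau_v_half_mV,
                 tau_v_slope_mV = tau_v_slope_mV),
            class = c("h_channel", "channel"))
}

#' Transient A-type potassium conductance model
#'
#' Classic transient-current kinetics `I = g_max * m^p * h * (V - e_rev)`
#' with fast activation (exponent `p`, default 3) and slower inactivation,
#' both first-order Boltzmann gates with constant time constants. The kinetic
#' scheme and parameter defaults are fixtures chosen to reproduce the
#' qualitative Kv4 behaviour (resting inactivation at holding, removal by a
#' hyperpolarizing prepulse, maximal activation at +60 mV).
#'
#' @param g_max_uS Maximal conductance, uS.
#' @param e_rev_mV Potassium reversal potential, mV (assumed -80).
#' @param act_v_half_mV,act_v_slope_mV,act_tau_ms Activation gate: midpoint,
#'   slope (negative: activated by depolarization), time constant.
#' @param act_exponent Activation gate exponent.
#' @param inact_v_half_mV,inact_v_slope_mV,inact_tau_ms Inactivation gate.
#' @return An object of class `a_channel`.
#' @export
a_channel <- function(g_max_uS, e_rev_mV = -80,
                      act_v_half_mV = -30, act_v_slope_mV = -10,
                      act_tau_ms = 10, act_exponent = 3,
                      inact_v_half_mV = -60, inact_v_slope_mV = 6,
                      inact_tau_ms = 80) {
  check_number(g_max_uS, "g_max_uS", lower = 0)
  if (act_v_slope_mV == 0 || inact_v_slope_mV == 0) {
    abort("gate slopes must be nonzero.")
  }
  check_positive(act_tau_ms, "act_tau_ms")
  check_positive(inact_tau_ms, "inact_tau_ms")
  check_positive(act_exponent, "act_exponent")
  structure(list(g_max_uS = g_max_uS, e_rev_mV = e_rev_mV,
                 act_v_half_mV = act_v_half_mV, act_v_slope_mV = act_v_slope_mV,
                 act_tau_ms = act_tau_ms, act_exponent = act_exponent,
                 inact_v_half_mV = inact_v_half_mV,
                 inact_v_slope_mV = inact_v_slope_mV,
                 inact_tau_ms = inact_tau_ms),
            class = c("a_channel", "channel"))
}

#' Boltzmann gating steady state
#'
#' `m_inf(V) = 1 / (1 + exp((V - v_half) / v_slope))`. With a positive slope
#' the gate opens on hyperpolarization (value -> 1 as V -> -Inf); with a
#' negative slope it opens on depolarization.
#'
#' @param v Membrane potential(s), mV.
#' @param v_half_mV Midpoint, mV.
#' @param v_slope_mV Slope factor, mV (nonzero).
#' @return Gate open fraction(s) in (0, 1).
#' @examples
#' gate_steady_state(-95, -95, 8) # 0.5
#' @export
gate_steady_state <- function(v, v_half_mV, v_slope_mV) {
  if (v_slope_mV == 0) abort("`v_slope_mV` must be nonzero.")
  1 / (1 + exp((v - v_half_mV) / v_slope_mV))
}

#' Voltage-dependent activation time constant (bell shape)
#'
#' `tau(V) = tau_max / cosh((V - tau_v_half) / tau_v_slope)`; strictly
#' positive everywhere, maximal at `tau_v_half`.
#'
#' @param v Membrane potential(s), mV.
#' @param tau_max_ms,tau_v_half_mV,tau_v_slope_mV Bell parameters.
#' @return Time constant(s), ms.
#' @export
gate_tau <- function(v, tau_max_ms, tau_v_half_mV, tau_v_slope_mV) {
  tau_max_ms / cosh((v - tau_v_half_mV) / tau_v_slope_mV)
}

#' Advance a gating variable one forward-Euler step
#'
#' `m <- m + dt * (m_inf(v) - m) / tau`, clamped to \[0, 1\]. A warning is
#' issued when `dt > tau` (the explicit step is outside its stability
#' region); the value is still clamped.
#'
#' @param m Current gate value in \[0, 1\].
#' @param v Membrane potential, mV.
#' @param dt_ms Time step, ms.
#' @param v_half_mV,v_slope_mV Steady-state Boltzmann parameters.
#' @param tau_ms Time constant at `v`, ms.
#' @return Updated gate value.
#' @export
advance_gate <- function(m, v, dt_ms, v_half_mV, v_slope_mV, tau_ms) {
  check_positive(dt_ms, "dt_ms")
  if (any(dt_ms > tau_ms)) {
    warn(sprintf("dt (%g ms) exceeds tau (%g ms); forward Euler is unstable here.",
                 dt_ms, min(tau_ms)))
  }
  pmin(1, pmax(0, m + dt_ms * (gate_steady_state(v, v_half_mV, v_slope_mV) - m) / tau_ms))
}

# steady-state gate values of a channel at a holding potential
channel_steady_state <- function(channel, v) {
  if (inherits(channel, "h_channel")) {
    list(m = gate_steady_state(v, channel$v_half_mV, channel$v_slope_mV))
  } else {
    list(m = gate_steady_state(v, channel$act_v_half_mV, channel$act_v_slope_mV),
         h = gate_steady_state(v, channel$inact_v_half_mV, channel$inact_v_slope_mV))
  }
}

#' Instantaneous channel current
#'
#' `I_h = g_max * m * (V - e_rev)`; `I_A = g_max * m^p * h * (V - e_rev)`.
#' uS times mV gives nA.
#'
#' @param channel An [h_channel()] or [a_channel()].
#' @param state Named list with gate value(s) `m` (and `h` for the A-current),
#'   e.g. from `channel_steady_state()` or a gating simulation.
#' @param v Membrane potential(s), mV.
#' @return Current(s), nA.
#' @export
channel_current <- function(channel, state, v) {
  if (inherits(channel, "h_channel")) {
    channel$g_max_uS * state$m * (v - channel$e_rev_mV)
  } else {
    channel$g_max_uS * state$m^channel$act_exponent * state$h * (v - channel$e_rev_mV)
  }
}

# Integrate a channel's gates along a sampled voltage trace (forward Euler,
# causal) and return the per-sample current, nA.
channel_current_trace <- function(channel, v, dt_ms, init = NULL) {
  init <- init %||% channel_steady_state(channel, v[1L])
  if (inherits(channel, "h_channel")) {
    m <- euler_gate_cpp(v, dt_ms, channel$v_half_mV, channel$v_slope_mV,
                        channel$tau_max_ms, channel$tau_v_half_mV,
                        channel$tau_v_slope_mV, init$m)
    channel$g_max_uS * m * (v - channel$e_rev_mV)
  } else {
    m <- euler_gate_cpp(v, dt_ms, channel$act_v_half_mV, channel$act_v_slope_mV,
                        channel$act_tau_ms, NA_real_, NA_real_, init$m)
    h <- euler_gate_cpp(v, dt_ms, channel$inact_v_half_mV, channel$inact_v_slope_mV,
                        channel$inact_tau_ms, NA_real_, NA_real_, init$h)
    channel$g_max_uS * m^channel$act_exponent * h * (v - channel$e_rev_mV)
  }
}

#' Offline dynamic-clamp current stream
#'
#' Replays a measured (or synthetic) voltage trace through the h-current
#' model exactly as a real-time dynamic clamp would: per-sample forward-Euler
#' gating, with the current at sample n computed from the state advanced
#' using sample n-1. The output is `scale * g_max * m * (V - e_rev)`; `scale`
#' implements the "measured G_max times predicted fold-change" convention
#' used to add or subtract a predicted conductance change.
#'
#' @param voltage A voltage [sampled_trace()].
#' @param channel An [h_channel()].
#' @param scale Dimensionless multiplier on the conductance.
#' @return A current `sampled_trace` on the same time grid.
#' @export
dynamic_clamp_stream <- function(voltage, channel, scale = 1) {
  stopifnot(inherits(voltage, "sampled_trace"),
            identical(attr(voltage, "kind"), "voltage"),
            inherits(channel, "h_channel"))
  check_number(scale, "scale", lower = 0)
  v <- trace_values(voltage)
  i <- scale * channel_current_trace(channel, v, trace_dt(voltage))
  new_trace_like(voltage, i, kind = "current",
                 meta = c(trace_meta(voltage), list(scale = scale)))
}
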