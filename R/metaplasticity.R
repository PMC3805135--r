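#' Calibrate the dopamine-enabled activity-dependence curve
#'
#' Dopamine does not modulate the h-current directly; it confers activity
#' dependence on its maximal conductance. The rule maps an activity index
#' (percent change in burst duration relative to the pre-dopamine baseline,
#' plus a cycle-frequency term and a spike-gating mode) to a target
#' fold-change of `G_max`:
#'
#' `F(x, f) = Boltzmann(x) * freq_factor^(f / 10)`
#'
#' where `x` is the percent change in burst duration, `f` the percent change
#' in cycle frequency, and `Boltzmann(x) = bottom + (top - bottom) /
#' (1 + exp((x - x_half) / x_slope))`, monotone non-increasing in `x`.
#'
#' Calibration anchors (micromolar mode): the curve passes through
#' `(-30, 0.94)` - a 30% burst-duration decrease should reduce `G_max` by
#' ~6% - given a fixed `top` and `x_slope` (assumed; the full curve is shown
#' only graphically), by solving for `x_half`. The frequency factor per +10%
#' cycle frequency is the ratio of the two measured folds, `0.87 / 0.94`.
#' Complete silence (`x <= -100`, the blocked-activity condition) pins the
#' target at `top`. Nanomolar mode instead anchors `F(0, 0) = 1` (no change
#' when baseline activity is mimicked) and has no calibrated frequency term.
#' Mode `"none"` (no dopamine) is the identity: no plasticity without
#' dopamine.
#'
#' @param da_mode `"micromolar"`, `"nanomolar"` or `"none"`.
#' @param top Fold asymptote as activity vanishes (assumed 1.10).
#' @param bottom Fold asymptote for large burst-duration increases
#'   (assumed 0.85).
#' @param x_slope Boltzmann slope over percent burst change (assumed 20).
#' @param anchor_burst_pct,anchor_fold The quantitative anchor the curve
#'   must pass through.
#' @param freq_anchor_fold Measured fold when the +10% frequency change is
#'   added to the anchor condition; sets `freq_factor_per_10pct`.
#' @param tau_ad_min Relaxation time constant of `G_max` toward its target,
#'   minutes.
#' @param patterned_tau_multiplier Slow-down factor applied to `tau_ad_min`
#'   when spike activity is mimicked as a patterned train.
#' @return An object of class `ad_curve`.
#' @examples
#' curve <- calibrate_ad_curve()
#' target_fold(curve, delta_burst_pct = -30) # 0.94
#' @export
calibrate_ad_curve <- function(da_mode = c("micromolar", "nanomolar", "none"),
                               top = 1.10, bottom = 0.85, x_slope = 20,
                               anchor_burst_pct = if (da_mode == "nanomolar") 0 else -30,
                               anchor_fold = if (da_mode == "nanomolar") 1.00 else 0.94,
                               freq_anchor_fold = 0.87,
                               tau_ad_min = 3,
                               patterned_tau_multiplier = 10) {
  da_mode <- match.arg(da_mode)
  check_positive(tau_ad_min, "tau_ad_min")
  check_positive(patterned_tau_multiplier, "patterned_tau_multiplier")
  if (da_mode == "none") {
    return(structure(list(da_mode = "none", tau_ad_min = tau_ad_min,
                          patterned_tau_multiplier = patterned_tau_multiplier),
                     class = "ad_curve"))
  }
  check_positive(x_slope, "x_slope")
  if (!(top > bottom && bottom > 0)) abort("need `top` > `bottom` > 0.")
  if (!(anchor_fold < top && anchor_fold > bottom)) {
    abort(sprintf(paste0("anchor fold %.3g is outside (bottom, top) = ",
                         "(%.3g, %.3g); a monotone Boltzmann cannot pass ",
                         "through it."), anchor_fold, bottom, top))
  }
  # solve for x_half: anchor_fold = bottom + (top-bottom)/(1+exp((x-xh)/s))
  x_half <- anchor_burst_pct -
    x_slope * log((top - bottom) / (anchor_fold - bottom) - 1)
  freq_factor <- if (da_mode == "micromolar") freq_anchor_fold / anchor_fold else 1
  provenance <- c(anchor = "measured", freq_factor = "ratio of measured folds",
                  top = "assumed", bottom = "assumed", x_slope = "assumed",
                  tau_ad_min = "assumed", patterned_tau_multiplier = "assumed")
  structure(list(da_mode = da_mode, top = top, bottom = bottom,
                 x_half = x_half, x_slope = x_slope,
                 anchor_burst_pct = anchor_burst_pct, anchor_fold = anchor_fold,
                 freq_factor_per_10pct = freq_factor,
                 tau_ad_min = tau_ad_min,
                 patterned_tau_multiplier = patterned_tau_multiplier,
                 provenance = provenance),
            class = "ad_curve")
}

#' @export
print.ad_curve <- function(x, ...) {
  cat(sprintf("<ad_curve: %s>\n", x$da_mode))
  if (x$da_mode != "none") {
    cat(sprintf("  Boltzmann top %.3g / bottom %.3g, x_half %.3g%%, x_slope %.3g%%\n",
                x$top, x$bottom, x$x_half, x$x_slope))
    cat(sprintf("  freq factor per +10%%: %.4g; tau_ad %.3g min (x%g patterned)\n",
                x$freq_factor_per_10pct, x$tau_ad_min, x$patterned_tau_multiplier))
  }
  invisible(x)
}

#' Target fold-change of the h-current G_max for a given activity pattern
#'
#' Without dopamine the target is exactly 1 (no plasticity). With dopamine,
#' a lumped spike-mimicking depolarization fully gates the rule (target 1);
#' otherwise the target is the calibrated Boltzmann over the burst-duration
#' change times the frequency factor, with complete silence
#' (`delta_burst_pct <= -100`) pinned at the curve top.
#'
#' @param curve An [calibrate_ad_curve()] object.
#' @param delta_burst_pct Percent change in burst duration vs baseline
#'   (-100 = silent).
#' @param delta_freq_pct Percent change in cycle frequency vs baseline.
#' @param spike_mode `"none"`, `"lumped"` or `"patterned"` spike mimicry.
#' @return Target fold (dimensionless, > 0).
#' @export
target_fold <- function(curve, delta_burst_pct, delta_freq_pct = 0,
                        spike_mode = c("none", "lumped", "patterned")) {
  stopifnot(inherits(curve, "ad_curve"))
  spike_mode <- match.arg(spike_mode)
  check_number(delta_burst_pct, "delta_burst_pct", lower = -100)
  check_number(delta_freq_pct, "delta_freq_pct")
  if (curve$da_mode == "none") return(1)
  if (spike_mode == "lumped") return(1)
  if (delta_burst_pct <= -100) return(curve$top)
  boltz <- curve$bottom + (curve$top - curve$bottom) /
    (1 + exp((delta_burst_pct - curve$x_half) / curve$x_slope))
  boltz * curve$freq_factor_per_10pct^(delta_freq_pct / 10)
}

#' Metaplastic G_max state
#'
#' Tracks the pre-dopamine maximal conductance `g0` and the current value
#' `g` as the activity-dependent rule relaxes it toward its target.
#'
#' @param g0_uS Pre-dopamine G_max, uS.
#' @param g_uS Current G_max, uS (defaults to `g0_uS`).
#' @return An object of class `metaplastic_state`.
#' @export
metaplastic_state <- function(g0_uS, g_uS = g0_uS) {
  check_positive(g0_uS, "g0_uS")
  check_positive(g_uS, "g_uS")
  structure(list(g0_uS = g0_uS, g_uS = g_uS, target_fold = NA_real_),
            class = "metaplastic_state")
}

#' Advance the metaplastic G_max by one time step
#'
#' First-order relaxation of `g` toward `target_fold * g0` with time
#' constant `tau_ad_min` (multiplied by `patterned_tau_multiplier` when the
#' activity carries patterned spike mimicry). The update uses the exact
#' exponential step `g <- target + (g - target) * exp(-dt / tau)`, so it is
#' unconditionally stable for any `dt`.
#'
#' @param state A [metaplastic_state()].
#' @param curve An [calibrate_ad_curve()] object.
#' @param delta_burst_pct,delta_freq_pct,spike_mode Activity index, as in
#'   [target_fold()].
#' @param dt_min Time step, minutes.
#' @return Updated `metaplastic_state` with `target_fold` recorded.
#' @export
advance_gmax <- function(state, curve, delta_burst_pct, delta_freq_pct = 0,
                         spike_mode = "none", dt_min) {
  stopifnot(inherits(state, "metaplastic_state"))
  check_positive(dt_min, "dt_min")
  fold <- target_fold(curve, delta_burst_pct, delta_freq_pct, spike_mode)
  tau <- curve$tau_ad_min *
    if (identical(spike_mode, "patterned")) curve$patterned_tau_multiplier else 1
  target <- fold * state$g0_uS
  state$g_uS <- target + (state$g_uS - target) * exp(-dt_min / tau)
  state$target_fold <- fold
  state
}
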