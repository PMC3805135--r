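#' Network preset: the statistical skeleton of a pyloric-like recording
#'
#' A `network_preset` fixes the deterministic structure of a paired
#' pacemaker (PD) / follower (LP) recording: cycle period, burst durations,
#' the LP-on delay from the last PD spike to the first LP spike, the
#' within-burst interspike interval, and Gaussian jitter magnitudes for cycle
#' onsets and individual spikes.
#'
#' Defaults describe a 1 Hz rhythm with LP firing at phase 0.25 for 300 ms,
#' order-of-magnitude consistent with spiny-lobster pyloric recordings at
#' room temperature. They are fixtures, not measurements. The LP spike count
#' defaults to `1 + lp_burst_ms / lp_mean_isi_ms` so the spike train spans
#' the full burst window; when the ratio is not an integer the generator
#' adapts the per-burst interval count so the realized mean ISI still tracks
#' `lp_mean_isi_ms` (see [generate_network_recording()]).
#'
#' @param cycle_period_ms Cycle period, ms (last PD spike to last PD spike).
#' @param pd_burst_ms PD burst duration, ms.
#' @param lp_burst_ms LP burst duration (first to last LP spike), ms.
#' @param lp_on_delay_ms Delay from last PD spike to first LP spike, ms.
#' @param lp_spikes_per_burst Nominal LP spikes per burst.
#' @param lp_mean_isi_ms Mean within-burst LP interspike interval, ms.
#' @param spike_jitter_sd_ms SD of per-spike Gaussian jitter, ms.
#' @param cycle_jitter_sd_ms SD of per-cycle onset jitter, ms.
#' @return An object of class `network_preset` (a named list).
#' @examples
#' p <- network_preset()
#' p$cycle_period_ms
#' @export
network_preset <- function(cycle_period_ms = 1000,
                           pd_burst_ms = 400,
                           lp_burst_ms = 300,
                           lp_on_delay_ms = 250,
                           lp_spikes_per_burst = 1 + round(lp_burst_ms / lp_mean_isi_ms),
                           lp_mean_isi_ms = 50,
                           spike_jitter_sd_ms = 2,
                           cycle_jitter_sd_ms = 20) {
  check_positive(cycle_period_ms, "cycle_period_ms")
  check_positive(pd_burst_ms, "pd_burst_ms")
  check_positive(lp_burst_ms, "lp_burst_ms")
  check_positive(lp_on_delay_ms, "lp_on_delay_ms")
  check_positive(lp_mean_isi_ms, "lp_mean_isi_ms")
  check_number(lp_spikes_per_burst, "lp_spikes_per_burst", lower = 2)
  check_number(spike_jitter_sd_ms, "spike_jitter_sd_ms", lower = 0)
  check_number(cycle_jitter_sd_ms, "cycle_jitter_sd_ms", lower = 0)
  if (lp_on_delay_ms + lp_burst_ms >= cycle_period_ms) {
    abort(paste0("`lp_on_delay_ms` + `lp_burst_ms` must be < `cycle_period_ms`; got ",
                 lp_on_delay_ms + lp_burst_ms, " >= ", cycle_period_ms, "."))
  }
  if (lp_mean_isi_ms * (lp_spikes_per_burst - 1) > lp_burst_ms + 1e-9) {
    abort(paste0("`lp_mean_isi_ms` * (`lp_spikes_per_burst` - 1) must be <= ",
                 "`lp_burst_ms`; got ",
                 lp_mean_isi_ms * (lp_spikes_per_burst - 1), " > ", lp_burst_ms, "."))
  }
  if (pd_burst_ms >= cycle_period_ms) {
    abort("`pd_burst_ms` must be < `cycle_period_ms`.")
  }
  structure(
    list(cycle_period_ms = cycle_period_ms,
         pd_burst_ms = pd_burst_ms,
         lp_burst_ms = lp_burst_ms,
         lp_on_delay_ms = lp_on_delay_ms,
         lp_spikes_per_burst = lp_spikes_per_burst,
         lp_mean_isi_ms = lp_mean_isi_ms,
         spike_jitter_sd_ms = spike_jitter_sd_ms,
         cycle_jitter_sd_ms = cycle_jitter_sd_ms),
    class = "network_preset")
}

#' Dopamine preset: multiplicative changes in network output
#'
#' Micromolar dopamine changes pyloric output in stereotyped ways: a
#' sustained ~10% reduction in cycle period, a ~30% decrease in LP burst
#' duration, a ~20% advance of the LP-on phase, a reduction of the mean
#' within-burst ISI to 66% of its initial value, and an immediate modulatory
#' reduction of the LP A-current maximal conductance to 81% of baseline.
#' Those five factors are this object's defaults.
#'
#' @param period_factor Fold applied to cycle period.
#' @param lp_burst_factor Fold applied to LP burst duration.
#' @param lp_on_phase_factor Fold applied to LP-on phase (b/a).
#' @param isi_factor Fold applied to the mean within-burst ISI.
#' @param ia_gmax_factor Fold applied to the A-current maximal conductance.
#' @return An object of class `da_preset`.
#' @export
da_preset <- function(period_factor = 0.90,
                      lp_burst_factor = 0.70,
                      lp_on_phase_factor = 0.80,
                      isi_factor = 0.66,
                      ia_gmax_factor = 0.81) {
  for (nm in c("period_factor", "lp_burst_factor", "lp_on_phase_factor",
               "isi_factor", "ia_gmax_factor")) {
    check_positive(get(nm), nm)
  }
  structure(
    list(period_factor = period_factor,
         lp_burst_factor = lp_burst_factor,
         lp_on_phase_factor = lp_on_phase_factor,
         isi_factor = isi_factor,
         ia_gmax_factor = ia_gmax_factor),
    class = "da_preset")
}

#' Apply a dopamine preset to a baseline network preset
#'
#' Scales the baseline: period by `period_factor`, LP burst duration by
#' `lp_burst_factor`, mean ISI by `isi_factor`; the LP-on delay is set so
#' that the new phase (delay/period) equals the baseline phase times
#' `lp_on_phase_factor`.
#'
#' @param base A [network_preset()].
#' @param da A [da_preset()].
#' @return A new `network_preset`.
#' @examples
#' apply_da_preset(network_preset(), da_preset())$cycle_period_ms # 900
#' @export
apply_da_preset <- function(base, da) {
  stopifnot(inherits(base, "network_preset"), inherits(da, "da_preset"))
  base_phase <- base$lp_on_delay_ms / base$cycle_period_ms
  new_period <- base$cycle_period_ms * da$period_factor
  network_preset(
    cycle_period_ms = new_period,
    pd_burst_ms = base$pd_burst_ms * da$period_factor,
    lp_burst_ms = base$lp_burst_ms * da$lp_burst_factor,
    lp_on_delay_ms = base_phase * da$lp_on_phase_factor * new_period,
    lp_spikes_per_burst = max(
      2, 1 + round(base$lp_burst_ms * da$lp_burst_factor /
                     (base$lp_mean_isi_ms * da$isi_factor))),
    lp_mean_isi_ms = base$lp_mean_isi_ms * da$isi_factor,
    spike_jitter_sd_ms = base$spike_jitter_sd_ms,
    cycle_jitter_sd_ms = base$cycle_jitter_sd_ms)
}

#' @export
print.network_preset <- function(x, ...) {
  cat("<network_preset>\n")
  for (nm in names(x)) cat(sprintf("  %-22s %g\n", nm, x[[nm]]))
  invisible(x)
}

#' @export
print.da_preset <- function(x, ...) {
  cat("<da_preset>\n")
  for (nm in names(x)) cat(sprintf("  %-20s %g\n", nm, x[[nm]]))
  invisible(x)
}
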