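#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a Boltzmann activation fit
#'
#' @param x A `boltzmann_fit`.
#' @param ... Unused.
#' @return One row per parameter: `term`, `estimate`.
#' @export
tidy.boltzmann_fit <- function(x, ...) {
  tibble(term = c("gmax_uS", "v_half_mV", "v_slope_mV"),
         estimate = c(x$gmax_uS, x$v_half_mV, x$v_slope_mV))
}

#' @rdname tidy.boltzmann_fit
#' @return For `glance()`: a one-row tibble with fit diagnostics.
#' @export
glance.boltzmann_fit <- function(x, ...) {
  tibble(gmax_uS = x$gmax_uS, v_half_mV = x$v_half_mV,
         v_slope_mV = x$v_slope_mV, rmse_uS = x$rmse_uS,
         n = nrow(x$data))
}

#' Tidy an activity-dependence curve
#'
#' @param x An `ad_curve`.
#' @param ... Unused.
#' @return One row per parameter with its provenance (measured anchor vs
#'   assumed shape parameter).
#' @export
tidy.ad_curve <- function(x, ...) {
  if (x$da_mode == "none") {
    return(tibble(term = "da_mode", estimate = NA_real_,
                  provenance = "identity (no dopamine, no plasticity)"))
  }
  terms <- c(top = x$top, bottom = x$bottom, x_half = x$x_half,
             x_slope = x$x_slope, anchor_burst_pct = x$anchor_burst_pct,
             anchor_fold = x$anchor_fold,
             freq_factor_per_10pct = x$freq_factor_per_10pct,
             tau_ad_min = x$tau_ad_min,
             patterned_tau_multiplier = x$patterned_tau_multiplier)
  prov <- c("assumed", "assumed", "solved from anchor", "assumed",
            "measured", "measured", "ratio of measured folds", "assumed",
            "assumed")
  tibble(term = names(terms), estimate = unname(terms), provenance = prov)
}

#' Tidy an experiment result
#'
#' @param x An `experiment_result`.
#' @param ... Unused.
#' @return Long tibble: `time_min`, `metric`, `value`.
#' @export
tidy.experiment_result <- function(x, ...) {
  as_tibble(x) |>
    tidyr::pivot_longer(-"time_min", names_to = "metric", values_to = "value",
                        values_transform = as.numeric)
}

#' @rdname tidy.experiment_result
#' @return For `glance()`: the final-time row with the target fold (clamp
#'   experiments) when available.
#' @export
glance.experiment_result <- function(x, ...) {
  out <- as_tibble(x[nrow(x), , drop = FALSE])
  tf <- attr(x, "target_fold")
  if (!is.null(tf)) out$target_fold <- tf
  out
}
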