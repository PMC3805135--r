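#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_segment
#'   geom_hline labs theme_minimal facet_wrap
NULL

#' @export
ggplot2::autoplot

#' Raster plot of a paired spike recording
#'
#' @param object A `spike_recording`.
#' @param ... Unused.
#' @return A ggplot: one row of ticks per cell.
#' @export
autoplot.spike_recording <- function(object, ...) {
  df <- as_tibble(object)
  ggplot(df, aes(x = .data$spike_time_ms / 1000, y = .data$cell_id)) +
    geom_point(shape = "|", size = 4) +
    labs(x = "time (s)", y = NULL, title = "PD / LP spike raster") +
    theme_minimal()
}

#' Activation curve and Boltzmann fit
#'
#' @param object A `boltzmann_fit`.
#' @param ... Unused.
#' @return A ggplot of measured conductance vs voltage with the fitted
#'   first-order Boltzmann overlaid.
#' @export
autoplot.boltzmann_fit <- function(object, ...) {
  grid <- tibble(v_mV = seq(min(object$data$v_mV), max(object$data$v_mV),
                            length.out = 200))
  grid$g_uS <- predict(object, grid$v_mV)
  ggplot(object$data, aes(x = .data$v_mV, y = .data$g_uS)) +
    geom_point() +
    geom_line(data = grid) +
    labs(x = "step potential (mV)", y = "conductance (uS)",
         title = sprintf("Boltzmann fit: gmax %.3g uS, V1/2 %.1f mV, slope %.1f mV",
                         object$gmax_uS, object$v_half_mV, object$v_slope_mV)) +
    theme_minimal()
}

#' Fold-change time courses of an experiment
#'
#' @param object An `experiment_result`.
#' @param metrics Columns to draw (defaults to every `*_fold` column).
#' @param ... Unused.
#' @return A ggplot of fold-changes vs time with the no-change line.
#' @export
autoplot.experiment_result <- function(object,
                                       metrics = grep("_fold$", names(object),
                                                      value = TRUE),
                                       ...) {
  df <- tidy.experiment_result(object) |>
    dplyr::filter(.data$metric %in% metrics)
  ggplot(df, aes(x = .data$time_min, y = .data$value, colour = .data$metric)) +
    geom_hline(yintercept = 1, linetype = "dashed", colour = "grey60") +
    geom_line() + geom_point() +
    labs(x = "time (min)", y = "fold-change vs t = 0", colour = NULL) +
    theme_minimal()
}

#' Plot a sampled trace
#'
#' @param object A `sampled_trace`.
#' @param downsample Keep every n-th sample for plotting speed.
#' @param ... Unused.
#' @return A ggplot of the trace.
#' @export
autoplot.sampled_trace <- function(object, downsample = 1L, ...) {
  df <- as_tibble(object)[seq(1, nrow(object), by = downsample), ]
  ylab <- if (identical(attr(object, "kind"), "voltage")) {
    "membrane potential (mV)"
  } else {
    "current (nA)"
  }
  ggplot(df, aes(x = .data$time_ms, y = .data[[names(df)[2]]])) +
    geom_line() +
    labs(x = "time (ms)", y = ylab) +
    theme_minimal()
}
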