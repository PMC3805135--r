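#' Segment a spike train into bursts by ISI threshold
#'
#' Groups consecutive spikes separated by at most `max_isi_ms` into bursts
#' and discards groups with fewer than `min_spikes` spikes. This is the
#' standard reconstruction of interactive burst marking: the default
#' threshold of three times the expected within-burst ISI cleanly separates
#' within-burst intervals from the inter-burst gap in rhythmic recordings.
#'
#' @param spikes Numeric vector of spike times (ms), sorted ascending, or a
#'   data frame with a `spike_time_ms` column (a single cell's train).
#' @param max_isi_ms Maximum within-burst interspike interval, ms.
#' @param min_spikes Minimum spikes per burst; smaller groups are dropped.
#' @return Tibble with one row per burst: `burst`, `first_spike_ms`,
#'   `last_spike_ms`, `n_spikes`, `mean_isi_ms` (NA for single-spike bursts).
#' @examples
#' detect_bursts(c(0, 10, 20, 500, 510), max_isi_ms = 100)
#' @export
detect_bursts <- function(spikes, max_isi_ms, min_spikes = 2) {
  check_positive(max_isi_ms, "max_isi_ms")
  check_number(min_spikes, "min_spikes", lower = 1)
  x <- check_sorted_spikes(spikes)
  if (length(x) == 0L) {
    return(tibble(burst = integer(), first_spike_ms = numeric(),
                  last_spike_ms = numeric(), n_spikes = integer(),
                  mean_isi_ms = numeric()))
  }
  grp <- cumsum(c(TRUE, diff(x) > max_isi_ms))
  tibble(spike_time_ms = x, grp = grp) |>
    dplyr::group_by(.data$grp) |>
    dplyr::summarise(first_spike_ms = min(.data$spike_time_ms),
                     last_spike_ms = max(.data$spike_time_ms),
                     n_spikes = dplyr::n(),
                     mean_isi_ms = if (dplyr::n() > 1)
                       mean(diff(.data$spike_time_ms)) else NA_real_,
                     .groups = "drop") |>
    dplyr::filter(.data$n_spikes >= min_spikes) |>
    dplyr::mutate(burst = dplyr::row_number(), .before = 1) |>
    dplyr::select(-"grp")
}

# convenience: burst tables for both cells of a recording
recording_bursts <- function(recording, max_isi_ms = NULL, min_spikes = 2) {
  preset <- attr(recording, "preset")
  max_isi_ms <- max_isi_ms %||% (3 * preset$lp_mean_isi_ms)
  split(recording$spike_time_ms, recording$cell_id) |>
    purrr::map(detect_bursts, max_isi_ms = max_isi_ms, min_spikes = min_spikes)
}

#' Per-cycle activity metrics from paired PD and LP burst tables
#'
#' Implements the cycle conventions used for pyloric recordings: the cycle
#' period `a` is the time between the last spike of one PD burst and the
#' last spike of the next; the LP-on delay `b` runs from the last PD spike
#' to the first LP spike of the LP burst assigned to that cycle; LP-on phase
#' is `b/a`; LP burst duration `c` is the first-to-last LP spike span. An LP
#' burst is assigned to cycle i when its first spike falls in the half-open
#' interval `(last_PD_i, last_PD_{i+1}]`. The LP-off delay is the last LP
#' spike minus the same cycle's last PD spike (mirroring the on-delay
#' convention). Cycles without an assignable LP burst are flagged with
#' `lp_missing = TRUE`, not dropped.
#'
#' @param pd,lp Burst tables from [detect_bursts()] for the PD and LP cells.
#' @return Tibble with one row per cycle: `cycle`, `a_ms`, `b_ms`, `c_ms`,
#'   `lp_off_delay_ms`, `lp_on_phase`, `lp_off_phase`, `mean_isi_ms`,
#'   `spikes_per_burst`, `lp_missing`.
#' @examples
#' pd <- detect_bursts(c(990, 1000, 1990, 2000), max_isi_ms = 50)
#' lp <- detect_bursts(c(1250, 1300, 1350), max_isi_ms = 100)
#' cycle_metrics(pd, lp)
#' @export
cycle_metrics <- function(pd, lp) {
  if (nrow(pd) < 2L) abort("need at least 2 PD bursts to define a cycle.")
  anchors <- pd$last_spike_ms
  n_cyc <- length(anchors) - 1L
  if (nrow(lp) == 0L) abort("LP burst table is empty.")

  # assign each LP burst to the cycle whose interval contains its first spike
  idx <- findInterval(lp$first_spike_ms, anchors, left.open = TRUE,
                      rightmost.closed = FALSE)
  rows <- purrr::map(seq_len(n_cyc), function(i) {
    j <- which(idx == i)
    a <- anchors[i + 1L] - anchors[i]
    if (length(j) == 0L) {
      return(tibble(cycle = i, a_ms = a, b_ms = NA_real_, c_ms = NA_real_,
                    lp_off_delay_ms = NA_real_, lp_on_phase = NA_real_,
                    lp_off_phase = NA_real_, mean_isi_ms = NA_real_,
                    spikes_per_burst = NA_real_, lp_missing = TRUE))
    }
    j <- j[1L]  # first assignable burst in the cycle
    b <- lp$first_spike_ms[j] - anchors[i]
    off <- lp$last_spike_ms[j] - anchors[i]
    tibble(cycle = i, a_ms = a, b_ms = b,
           c_ms = lp$last_spike_ms[j] - lp$first_spike_ms[j],
           lp_off_delay_ms = off,
           lp_on_phase = b / a, lp_off_phase = off / a,
           mean_isi_ms = lp$mean_isi_ms[j],
           spikes_per_burst = as.numeric(lp$n_spikes[j]),
           lp_missing = FALSE)
  })
  out <- dplyr::bind_rows(rows)
  if (mean(out$lp_missing) > 0.5) {
    abort(paste0("no assignable LP burst in more than half of the cycles; ",
                 "PD and LP inputs look mis-paired or LP lacks burst structure."))
  }
  out
}

#' Windowed (n-cycle) averages of cycle metrics
#'
#' Averages each metric over consecutive non-overlapping windows of `n`
#' cycles (default 10, the reporting convention for pyloric parameters).
#' Cycles flagged `lp_missing` contribute to the period average but not to
#' the LP metrics; their count per window is reported in `n_missing`.
#'
#' @param metrics Output of [cycle_metrics()].
#' @param n Cycles per window.
#' @return Tibble with one row per complete window: `window`, `n_cycles`,
#'   `n_missing`, and the window means of each metric column.
#' @export
windowed_average <- function(metrics, n = 10) {
  check_number(n, "n", lower = 1)
  if (nrow(metrics) < n) {
    abort(sprintf("need at least n = %d cycles; got %d.", n, nrow(metrics)))
  }
  metrics |>
    dplyr::mutate(window = (dplyr::row_number() - 1L) %/% n + 1L) |>
    dplyr::group_by(.data$window) |>
    dplyr::filter(dplyr::n() == n) |>
    dplyr::summarise(
      n_cycles = dplyr::n(),
      n_missing = sum(.data$lp_missing),
      dplyr::across(c("a_ms", "b_ms", "c_ms", "lp_off_delay_ms",
                      "lp_on_phase", "lp_off_phase", "mean_isi_ms",
                      "spikes_per_burst"),
                    ~ mean(.x, na.rm = TRUE)),
      .groups = "drop")
}

#' Normalize a metric time course to its value at a reference time
#'
#' Divides each value of the selected columns by the value in the row where
#' `time` equals `reference_time`, yielding fold-changes. Normalizing an
#' already-normalized series at the same reference is an identity.
#'
#' @param data A data frame with a time column and metric columns.
#' @param cols <tidy-select> Columns to normalize.
#' @param time <tidy-select> Time column (default `time_min`).
#' @param reference_time Reference time; its row must exist and the
#'   reference values must be nonzero.
#' @return `data` with the selected columns divided by their reference value.
#' @examples
#' df <- tibble::tibble(time_min = c(0, 10), phase = c(0.25, 0.20))
#' fold_change(df, phase, reference_time = 0)
#' @export
fold_change <- function(data, cols, time = time_min, reference_time = 0) {
  time_q <- rlang::enquo(time)
  tvals <- dplyr::pull(data, !!time_q)
  ref_row <- which(tvals == reference_time)
  if (length(ref_row) != 1L) {
    abort(sprintf("`reference_time` = %s must match exactly one row.",
                  format(reference_time)))
  }
  dplyr::mutate(data, dplyr::across({{ cols }}, function(x) {
    ref <- x[ref_row]
    if (!is.finite(ref) || ref == 0) abort("reference value is zero or missing.")
    x / ref
  }))
}
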