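#' Construct a uniformly sampled trace
#'
#' A `sampled_trace` is a tibble with a `time_ms` column and a value column
#' (`v_mV` for voltage, `i_nA` for current), plus attributes recording the
#' sampling interval and trace kind. All trace-consuming functions in the
#' package accept these objects.
#'
#' @param time_ms Sample times, ms (uniform grid).
#' @param value Sample values.
#' @param kind `"voltage"` (mV) or `"current"` (nA).
#' @param dt_ms Sampling interval; inferred from `time_ms` when `NULL`.
#' @param meta Optional named list of extra metadata (protocol windows etc.).
#' @return A tibble of class `sampled_trace`.
#' @export
sampled_trace <- function(time_ms, value, kind = c("voltage", "current"),
                          dt_ms = NULL, meta = list()) {
  kind <- match.arg(kind)
  stopifnot(length(time_ms) == length(value), length(time_ms) >= 2L)
  if (is.null(dt_ms)) dt_ms <- time_ms[2L] - time_ms[1L]
  col <- if (kind == "voltage") "v_mV" else "i_nA"
  out <- tibble(time_ms = as.numeric(time_ms))
  out[[col]] <- as.numeric(value)
  structure(out,
            class = c("sampled_trace", class(out)),
            dt_ms = dt_ms, kind = kind, units = if (kind == "voltage") "mV" else "nA",
            meta = meta)
}

trace_values <- function(trace) {
  kind <- attr(trace, "kind")
  trace[[if (identical(kind, "voltage")) "v_mV" else "i_nA"]]
}

trace_dt <- function(trace) attr(trace, "dt_ms")

trace_meta <- function(trace, key = NULL) {
  m <- attr(trace, "meta") %||% list()
  if (is.null(key)) m else m[[key]]
}

new_trace_like <- function(trace, value, kind, meta = NULL) {
  sampled_trace(trace$time_ms, value, kind = kind, dt_ms = trace_dt(trace),
                meta = meta %||% trace_meta(trace))
}

#' @export
print.sampled_trace <- function(x, ...) {
  cat(sprintf("<sampled_trace: %s, %d samples, dt = %g ms>\n",
              attr(x, "kind"), nrow(x), attr(x, "dt_ms")))
  NextMethod()
}
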