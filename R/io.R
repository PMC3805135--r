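# Config and result plumbing: YAML/JSON configs with unit-suffixed keys,
# spike-train CSV, trace CSV + JSON sidecar, and run manifests.

known_unit_suffixes <- c("_ms", "_mV", "_nA", "_uS", "_nF", "_min", "_pct")

# keys that are legitimately dimensionless
unitless_keys <- c(
  "seed", "cell_id", "spike_mode", "da_mode", "kind", "units", "n_cycles",
  "spike_count", "lp_spikes_per_burst", "period_factor", "lp_burst_factor",
  "lp_on_phase_factor", "isi_factor", "ia_gmax_factor", "ia_factor",
  "period_factor", "top", "bottom", "x_half", "x_slope",
  "freq_factor_per_10pct", "patterned_tau_multiplier", "act_exponent",
  "inhibition_duty", "addback", "scale", "anchor_fold", "anchor_burst_pct",
  "freq_anchor_fold", "g_uS", "e_mV", "n", "type", "preset", "duty")

#' Load and validate a configuration file
#'
#' Reads a YAML or JSON config (by extension) and validates its keys:
#' numeric scalar keys must carry a unit suffix (`_ms`, `_mV`, `_nA`,
#' `_uS`, `_nF`, `_min`, `_pct`) unless they are known dimensionless
#' parameters, and unknown keys are rejected when a `schema` of allowed
#' names is given. Nested sections are validated recursively.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @param schema Optional character vector of allowed top-level keys.
#' @return Named list of configuration values.
#' @export
load_config <- function(path, schema = NULL) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  cfg <- switch(ext,
                yaml = , yml = yaml::read_yaml(path),
                json = jsonlite::read_json(path, simplifyVector = TRUE),
                abort(sprintf("unsupported config format: .%s", ext)))
  if (!is.list(cfg)) abort("config must be a mapping of keys to values.")
  validate_config_keys(cfg, schema = schema)
  cfg
}

validate_config_keys <- function(cfg, schema = NULL, parent = "") {
  if (is.null(names(cfg)) || any(names(cfg) == "")) {
    abort(sprintf("all config entries%s must be named.",
                  if (nzchar(parent)) paste0(" under `", parent, "`") else ""))
  }
  if (!is.null(schema)) {
    bad <- setdiff(names(cfg), schema)
    if (length(bad)) {
      abort(sprintf("unknown config key(s): %s (allowed: %s).",
                    paste(bad, collapse = ", "), paste(schema, collapse = ", ")))
    }
  }
  for (nm in names(cfg)) {
    val <- cfg[[nm]]
    if (is.list(val)) {
      validate_config_keys(val, parent = nm)
    } else if (is.numeric(val) && !nm %in% unitless_keys) {
      if (!any(endsWith(nm, known_unit_suffixes))) {
        abort(sprintf(paste0("config key `%s` is numeric but has no unit ",
                             "suffix; expected one of: %s (or a known ",
                             "dimensionless name)."),
                      nm, paste(known_unit_suffixes, collapse = ", ")))
      }
    }
  }
  invisible(cfg)
}

#' Save a configuration list
#'
#' @param cfg Named list.
#' @param path Destination `.yaml`/`.yml` or `.json` path.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         yaml = , yml = yaml::write_yaml(cfg, path),
         json = jsonlite::write_json(cfg, path, auto_unbox = TRUE,
                                     digits = NA, pretty = TRUE),
         abort(sprintf("unsupported config format: .%s", ext)))
  invisible(path)
}

#' Write / read spike trains as two-column CSV
#'
#' The on-disk exchange format for spike recordings: columns `cell_id`,
#' `spike_time_ms`, header required, times printed with 9 significant
#' digits.
#'
#' @param recording Data frame with `cell_id` and `spike_time_ms`.
#' @param path CSV path.
#' @return `path` invisibly (write); a tibble (read).
#' @export
write_spike_csv <- function(recording, path) {
  stopifnot(all(c("cell_id", "spike_time_ms") %in% names(recording)))
  df <- data.frame(cell_id = recording$cell_id,
                   spike_time_ms = signif(recording$spike_time_ms, 9))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_spike_csv
#' @export
read_spike_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("cell_id", "spike_time_ms") %in% names(df))) {
    abort("spike CSV must have columns `cell_id`, `spike_time_ms`.")
  }
  as_tibble(df)
}

#' Write / read a sampled trace as CSV plus JSON sidecar
#'
#' The trace samples go to `<path>` (columns `time_ms`, `value`); the
#' metadata (units, dt, kind, and any protocol info) goes to
#' `<path>.json`.
#'
#' @param trace A [sampled_trace()].
#' @param path CSV path.
#' @return `path` invisibly (write); a `sampled_trace` (read).
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "sampled_trace"))
  df <- data.frame(time_ms = signif(trace$time_ms, 9),
                   value = signif(trace_values(trace), 9))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  sidecar <- list(units = attr(trace, "units"), dt_ms = attr(trace, "dt_ms"),
                  kind = attr(trace, "kind"), meta = attr(trace, "meta"))
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  df <- utils::read.csv(path)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  meta <- side$meta
  if (is.data.frame(meta)) meta <- as.list(meta)
  sampled_trace(df$time_ms, df$value, kind = side$kind, dt_ms = side$dt_ms,
                meta = if (length(meta)) meta else list())
}

#' Write an experiment result with a run manifest
#'
#' Writes a tidy long CSV (`time_min`, `metric`, `value`; deterministic
#' column and row order, 9 significant digits), a JSON summary of the final
#' row, and a `manifest.json` recording the package version, seed (when the
#' result carries one), and output file list.
#'
#' @param result An `experiment_result` (from [run_clamp_experiment()] or
#'   [run_network_experiment()]) or any data frame with a `time_min`
#'   column.
#' @param dir Output directory (created if needed).
#' @param name Stem used for the file names.
#' @return Invisibly, the manifest as a list.
#' @export
write_result <- function(result, dir, name = "experiment") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  long <- result |>
    as_tibble() |>
    tidyr::pivot_longer(-"time_min", names_to = "metric", values_to = "value",
                        values_transform = as.numeric) |>
    dplyr::arrange(.data$time_min, .data$metric) |>
    dplyr::mutate(value = signif(.data$value, 9))
  csv_path <- file.path(dir, paste0(name, ".csv"))
  utils::write.csv(as.data.frame(long), csv_path, row.names = FALSE, quote = FALSE)

  summary_path <- file.path(dir, paste0(name, "_summary.json"))
  final <- result[nrow(result), , drop = FALSE]
  jsonlite::write_json(as.list(final), summary_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  cfg <- attr(result, "config")
  manifest <- list(
    package = "pyloop",
    version = as.character(utils::packageVersion("pyloop")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = if (!is.null(cfg$seed)) cfg$seed else NULL,
    outputs = c(basename(csv_path), basename(summary_path)))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
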