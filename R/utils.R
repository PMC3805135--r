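#' @importFrom rlang abort warn %||% .data
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom generics tidy glance
#' @useDynLib pyloop, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Validation helpers. Every user-facing constructor funnels through these so
# that an invariant-violating input names the offending field.

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         allow_null = FALSE) {
  if (is.null(x)) {
    if (allow_null) return(invisible(x))
    abort(sprintf("`%s` must be supplied.", name))
  }
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (x < lower || x > upper) {
    abort(sprintf("`%s` must be in [%s, %s]; got %s.", name,
                  format(lower), format(upper), format(x)))
  }
  invisible(x)
}

check_positive <- function(x, name) check_number(x, name, lower = .Machine$double.xmin)

check_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be TRUE or FALSE.", name))
  }
  invisible(x)
}

check_sorted_spikes <- function(x, name = "spike_times") {
  if (is.data.frame(x)) x <- x$spike_time_ms
  if (!is.numeric(x)) abort(sprintf("`%s` must be numeric spike times (ms).", name))
  if (anyNA(x)) abort(sprintf("`%s` contains missing values.", name))
  if (is.unsorted(x, strictly = FALSE)) {
    abort(sprintf("`%s` must be sorted ascending.", name))
  }
  x
}

# Derive a named substream seed from a top-level seed so that independent
# modules draw from independent streams but everything is reproducible from
# one integer. Kept below 2^31 - 1 (R integers are 32-bit).
substream_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
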