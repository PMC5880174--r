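#' Uniformly sampled signal trace
#'
#' The basic container for every signal handled by the package: a recorded
#' bipolar potential difference, a derived impulse-energy series, or a
#' synthetic signal with known scaling properties.
#'
#' @param values numeric vector of samples; all finite, length >= 2.
#' @param dt sampling interval in seconds (> 0).
#' @param t_start time of the first sample in seconds.
#' @param label short text label carried through the pipeline.
#' @param units physical units of `values` (free text).
#' @return An object of class `signal_trace`: a list with fields `values`,
#'   `dt`, `t_start`, `label`, `units`.
#' @examples
#' tr <- signal_trace(sin(seq(0, 2 * pi, length.out = 256)), dt = 1e-3)
#' length(tr$values)
#' @export
signal_trace <- function(values, dt, t_start = 0, label = "signal", units = "a.u.") {
  values <- as.numeric(values)
  if (length(values) < 2L)
    stop("invalid-input: a signal_trace needs at least 2 samples", call. = FALSE)
  if (!all(is.finite(values)))
    stop("invalid-input: signal values must all be finite", call. = FALSE)
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop("invalid-parameter: dt must be a positive scalar", call. = FALSE)
  structure(
    list(values = values, dt = as.numeric(dt), t_start = as.numeric(t_start),
         label = as.character(label)[1L], units = as.character(units)[1L]),
    class = "signal_trace")
}

#' @export
print.signal_trace <- function(x, ...) {
  cat(sprintf("<signal_trace> %s: %d samples, dt = %g s (%.4g s span), units = %s\n",
              x$label, length(x$values), x$dt,
              (length(x$values) - 1L) * x$dt, x$units))
  invisible(x)
}

#' @export
length.signal_trace <- function(x) length(x$values)

#' Sample times of a trace
#' @param trace a [signal_trace()].
#' @return numeric vector of sample times in seconds.
#' @export
trace_times <- function(trace) {
  stopifnot(inherits(trace, "signal_trace"))
  trace$t_start + (seq_along(trace$values) - 1L) * trace$dt
}

#' Read a signal trace from delimited text
#'
#' Expects one header line with column names (`time_s` plus one value column,
#' or `time_s, value_Pt1 .. value_Pt5` for multi-channel files); comment lines
#' start with `#`. The time column must be uniformly sampled.
#'
#' @param path file path.
#' @param channel column name or index (counted among value columns) to read.
#' @param sep field separator, default whitespace/tab autodetected by
#'   [utils::read.table()].
#' @return a [signal_trace()].
#' @export
read_signal_trace <- function(path, channel = 1L, sep = "") {
  df <- utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                          check.names = FALSE)
  if (!"time_s" %in% names(df))
    stop("invalid-input: expected a 'time_s' column", call. = FALSE)
  tm <- df[["time_s"]]
  vals_cols <- setdiff(names(df), "time_s")
  if (length(vals_cols) == 0L)
    stop("invalid-input: no value column found", call. = FALSE)
  col <- if (is.character(channel)) channel else vals_cols[[channel]]
  if (!col %in% vals_cols)
    stop(sprintf("invalid-parameter: channel '%s' not present", col), call. = FALSE)
  dts <- diff(tm)
  if (length(dts) < 1L || any(abs(dts - dts[1L]) > 1e-6 * abs(dts[1L]) + 1e-12))
    stop("invalid-input: time column is not uniformly sampled", call. = FALSE)
  signal_trace(df[[col]], dt = dts[1L], t_start = tm[1L], label = col)
}

#' Write a signal trace to 2-column delimited text
#'
#' Writes `time_s` and `value` columns with a header line, the format read
#' back by [read_signal_trace()].
#'
#' @param trace a [signal_trace()].
#' @param path output file path.
#' @param sep field separator (default tab).
#' @return `path`, invisibly.
#' @export
write_signal_trace <- function(trace, path, sep = "\t") {
  stopifnot(inherits(trace, "signal_trace"))
  df <- data.frame(time_s = trace_times(trace), value = trace$values)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Run code with a locally seeded RNG, restoring the caller's RNG state.
# All generators in the package are pure functions of (spec, seed).
with_seed <- function(seed, code) {
  if (!is.null(old <- globalenv()$.Random.seed)) {
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}
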