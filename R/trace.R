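#' Uniformly sampled membrane-potential trace
#'
#' A minimal container for a uniformly sampled time series. Values are in mV,
#' time in ms throughout the package.
#'
#' @param data numeric vector of samples (mV).
#' @param dt sample interval in ms (default 0.02 ms, i.e. 50 kHz).
#' @param t0 time of the first sample in ms (default 0).
#' @return an object of class `syn_trace` with fields `data`, `dt`, `t0`.
#' @export
new_trace <- function(data, dt = 0.02, t0 = 0) {
  stopifnot(is.numeric(data), length(dt) == 1L, dt > 0)
  structure(list(data = as.numeric(data), dt = dt, t0 = t0),
            class = "syn_trace")
}

#' Sample times of a trace
#' @param trace a `syn_trace`.
#' @return numeric vector of times in ms.
#' @export
trace_times <- function(trace) {
  trace$t0 + (seq_along(trace$data) - 1L) * trace$dt
}

#' @export
print.syn_trace <- function(x, ...) {
  cat(sprintf("<syn_trace> %d samples @ %.4g kHz, t = [%.3g, %.3g] ms\n",
              length(x$data), 1 / x$dt, x$t0,
              x$t0 + (length(x$data) - 1L) * x$dt))
  invisible(x)
}

# index of the sample closest to time t (ms); clamped to valid range
trace_index <- function(trace, t) {
  i <- round((t - trace$t0) / trace$dt) + 1L
  pmin(pmax(as.integer(i), 1L), length(trace$data))
}

# extract samples in [t_from, t_to] (ms, inclusive)
trace_window <- function(trace, t_from, t_to) {
  i <- trace_index(trace, t_from)
  j <- trace_index(trace, t_to)
  trace$data[i:j]
}
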