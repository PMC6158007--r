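# Exponential deconvolution D(t) = V + tau * dV/dt, and per-pulse train
# amplitude measurement. The deconvolution removes first-order membrane
# filtering, undoing temporal summation within stimulus trains.

# centered finite differences, forward/backward at the edges
centered_diff <- function(v, dt) {
  n <- length(v)
  d <- numeric(n)
  if (n < 2) return(d)
  d[2:(n - 1)] <- (v[3:n] - v[1:(n - 2)]) / (2 * dt)
  d[1] <- (v[2] - v[1]) / dt
  d[n] <- (v[n] - v[n - 1]) / dt
  d
}

#' Exponential deconvolution of a trace
#'
#' Computes \eqn{D(t) = V(t) + \tau \, dV/dt}. The default derivative uses
#' centered finite differences; `method = "recursive"` uses a backward
#' difference whose exact discrete inverse is [reconvolve()], giving
#' bit-stable round trips.
#'
#' @param trace a `syn_trace`.
#' @param tau deconvolution time constant, ms (default 15).
#' @param method `"centered"` or `"recursive"`.
#' @return a `syn_trace` of deconvolved samples, same grid as the input.
#' @export
deconvolve <- function(trace, tau = 15, method = c("centered", "recursive")) {
  if (tau <= 0) stop_invalid("tau must be positive")
  method <- match.arg(method)
  v <- trace$data
  d <- if (method == "centered") {
    v + tau * centered_diff(v, trace$dt)
  } else {
    r <- tau / trace$dt
    c(v[1], v[-1] + r * diff(v))
  }
  out <- new_trace(d, dt = trace$dt, t0 = trace$t0)
  attr(out, "tau") <- tau
  attr(out, "method") <- method
  out
}

#' Reconvolve a deconvolved trace
#'
#' Inverse of [deconvolve()]: passes `D` through a first-order low-pass with
#' time constant `tau`. For `method = "recursive"` this is the exact discrete
#' inverse of the backward-difference deconvolution.
#'
#' @inheritParams deconvolve
#' @export
reconvolve <- function(trace, tau = 15, method = c("centered", "recursive")) {
  if (tau <= 0) stop_invalid("tau must be positive")
  method <- match.arg(method)
  d <- trace$data
  n <- length(d)
  v <- numeric(n)
  v[1] <- d[1]
  if (method == "recursive") {
    r <- tau / trace$dt
    for (i in 2:n) v[i] <- (d[i] + r * v[i - 1]) / (1 + r)
  } else {
    # exact exponential step for piecewise-linear D
    h <- trace$dt
    e <- exp(-h / tau)
    # solution of tau v' + v = D with D linear on each step
    a <- d[-n]; b <- (d[-1] - d[-n]) / h
    for (i in 2:n)
      v[i] <- v[i - 1] * e + (a[i - 1] + b[i - 1] * (h - tau)) -
        (a[i - 1] - b[i - 1] * tau) * e
  }
  new_trace(v, dt = trace$dt, t0 = trace$t0)
}

#' Per-pulse train amplitudes from deconvolved average
#'
#' Averages the sweeps, deconvolves (tau default 15 ms), applies a zero-phase
#' low-pass filter, and measures the peak of the deconvolved trace in a
#' window after each presynaptic pulse. The window starts 1 ms after the
#' spike and ends at half the interval to the next spike, capped at 15 ms, so
#' windows never collide even at 100 Hz.
#'
#' Each pulse's amplitude is its window peak minus the local pre-pulse
#' baseline (mean of the `baseline_ms` immediately preceding the spike),
#' which removes the residual slow tail left when the deconvolution time
#' constant differs from the true membrane time constant.
#'
#' @param sweeps list of `syn_sweep` sharing one grid and protocol.
#' @param tau deconvolution time constant, ms.
#' @param lowpass_khz post-deconvolution low-pass cutoff, kHz (default 1).
#' @param window_start_ms offset of window start after each spike (default 1).
#' @param window_cap_ms maximum window length (default 15).
#' @param baseline_ms local pre-pulse baseline length, ms (default 1).
#' @return list with `absolute` (mV-equivalent peak per pulse), `normalized`
#'   (relative to pulse 1), and the `windows` used.
#' @export
train_amplitudes <- function(sweeps, tau = 15, lowpass_khz = 1,
                             window_start_ms = 1, window_cap_ms = 15,
                             baseline_ms = 1) {
  if (length(sweeps) < 1) stop_invalid("at least one sweep required")
  st <- sweeps[[1]]$spike_times
  avg <- average_sweeps(sweeps)
  d <- deconvolve(avg, tau)
  d$data <- butter_filtfilt(d$data, lowpass_khz, d$dt)
  gaps <- c(diff(st), Inf)
  w_end <- pmin(window_cap_ms, gaps / 2)
  if (any(w_end <= window_start_ms))
    stop_invalid("empty pulse window: inter-pulse interval too short")
  peaks <- vapply(seq_along(st), function(k) {
    base <- mean(trace_window(d, st[k] - baseline_ms, st[k]))
    max(trace_window(d, st[k] + window_start_ms, st[k] + w_end[k])) - base
  }, numeric(1))
  list(absolute = peaks, normalized = peaks / peaks[1],
       windows = cbind(start = st + window_start_ms, end = st + w_end))
}

#' Short-term plasticity ratios from a normalized pulse train
#'
#' Ratios of pulse-1-normalized amplitudes quantifying steady-state
#' depression (8:1), recovery after the delay (9:1) and paired-pulse
#' facilitation (2:1).
#'
#' @param normalized per-pulse amplitudes normalized to pulse 1 (>= 9 pulses).
#' @export
stp_ratios <- function(normalized) {
  if (length(normalized) < 9) stop_invalid("need >= 9 pulses for STP ratios")
  list(induction_8_1 = normalized[8] / normalized[1],
       recovery_9_1 = normalized[9] / normalized[1],
       paired_pulse_2_1 = normalized[2] / normalized[1])
}

# mean of aligned sweep traces (all sweeps must share the grid)
average_sweeps <- function(sweeps) {
  if (length(sweeps) == 0) stop_invalid("no sweeps to average")
  tr1 <- sweeps[[1]]$trace
  m <- vapply(sweeps, function(s) {
    if (length(s$trace$data) != length(tr1$data) || s$trace$dt != tr1$dt)
      stop_invalid("sweeps do not share a common sampling grid")
    s$trace$data
  }, numeric(length(tr1$data)))
  new_trace(rowMeans(m), dt = tr1$dt, t0 = tr1$t0)
}
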