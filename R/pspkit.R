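# Sweep quality control, spike-aligned averaging, double-exponential PSP
# fitting with region-weighted error, kinetics extraction, CV and run-down.

#' Quality control of a single sweep
#'
#' Applies the per-sweep inclusion rules: auto-bias current below 800 pA,
#' baseline within +-5 mV of the target holding potential, baseline mean
#' (10 ms preceding stimulation) within 3 SD of the across-sweep baseline
#' mean, no spontaneous postsynaptic spikes (threshold -20 mV), and a
#' stimulus artifact below 30 uV in the masked crosstalk window. All failures
#' are reported, not just the first.
#'
#' @param sweep a `syn_sweep` with >= 10 ms pre-stimulus baseline.
#' @param target_holding target holding potential, mV (default -70).
#' @param baseline_stats optional list `(mean, sd)` of across-sweep baseline
#'   means (supplied by [qc_connection()]); the outlier check is skipped when
#'   `NULL`.
#' @param drift_mv,bias_pa_max,spike_mv,artifact_mv QC thresholds.
#' @return list `(passed, reasons)`; `passed` is `TRUE` iff `reasons` is
#'   empty.
#' @export
qc_sweep <- function(sweep, target_holding = -70, baseline_stats = NULL,
                     drift_mv = 5, bias_pa_max = 800, spike_mv = -20,
                     artifact_mv = 0.030) {
  first_spike <- min(sweep$spike_times)
  if (first_spike - sweep$trace$t0 < 10)
    stop_invalid("sweep needs >= 10 ms pre-stimulus baseline")
  reasons <- character(0)
  if (abs(sweep$bias_current) >= bias_pa_max)
    reasons <- c(reasons, "bias_current")
  bl <- trace_window(sweep$trace, first_spike - 10, first_spike)
  if (abs(mean(bl) - target_holding) > drift_mv)
    reasons <- c(reasons, "baseline_drift")
  if (!is.null(baseline_stats) && baseline_stats$sd > 0 &&
      abs(mean(bl) - baseline_stats$mean) > 3 * baseline_stats$sd)
    reasons <- c(reasons, "baseline_outlier")
  if (any(sweep$trace$data > spike_mv))
    reasons <- c(reasons, "spontaneous_spike")
  # crosstalk artifact: deviation of the stimulus window from the linear
  # trend of the preceding 1.5 ms (so slow PSP tails from earlier pulses in
  # the train do not register as artifacts)
  # a crosstalk artifact is a fast transient confined to the stimulus
  # window; smooth PSP tails from earlier pulses are removed by
  # extrapolating a quadratic trend fitted on the preceding 3 ms
  art <- vapply(sweep$spike_times, function(s) {
    pre <- trace_window(sweep$trace, s - 3.5, s - 0.5)
    w <- trace_window(sweep$trace, s - 0.5, s + 0.5)
    tp <- seq_along(pre)
    co <- stats::coef(stats::lm(pre ~ tp + I(tp^2)))
    tw <- length(pre) + seq_along(w)
    abs(mean(w) - mean(co[[1]] + co[[2]] * tw + co[[3]] * tw^2))
  }, numeric(1))
  if (max(art) >= artifact_mv) reasons <- c(reasons, "artifact")
  list(passed = length(reasons) == 0L, reasons = reasons)
}

#' Quality control of a connection (sweep set)
#'
#' Filters sweeps through [qc_sweep()] using across-sweep baseline statistics
#' and requires a minimum number of surviving sweeps. With
#' `readmit_depolarized = TRUE` (used for short-term-plasticity analysis),
#' sweeps held at -55 +- 5 mV are re-admitted against that target.
#'
#' @param sweeps list of `syn_sweep`.
#' @param target_holding target holding potential, mV.
#' @param min_sweeps minimum QC-passed sweeps (default 5).
#' @param readmit_depolarized also accept sweeps near -55 mV holding.
#' @param ... further thresholds passed to [qc_sweep()].
#' @return list with `included` (passing sweeps), `qc` `(passed, reasons)`,
#'   and per-sweep results `per_sweep`.
#' @export
qc_connection <- function(sweeps, target_holding = -70, min_sweeps = 5L,
                          readmit_depolarized = FALSE, ...) {
  bl_means <- vapply(sweeps, function(s) {
    fs <- min(s$spike_times)
    mean(trace_window(s$trace, fs - 10, fs))
  }, numeric(1))
  stats_ <- list(mean = mean(bl_means), sd = stats::sd(bl_means))
  per <- lapply(sweeps, function(s) {
    r <- qc_sweep(s, target_holding, baseline_stats = stats_, ...)
    if (!r$passed && readmit_depolarized && "baseline_drift" %in% r$reasons) {
      r55 <- qc_sweep(s, target_holding = -55, baseline_stats = NULL, ...)
      if (r55$passed) r <- r55
    }
    r
  })
  ok <- vapply(per, `[[`, logical(1), "passed")
  included <- sweeps[ok]
  reasons <- character(0)
  if (sum(ok) < min_sweeps) reasons <- "min_sweeps"
  list(included = included,
       qc = list(passed = length(reasons) == 0L, reasons = reasons),
       per_sweep = per)
}

#' Spike-aligned average response for one pulse
#'
#' Extracts the response window around the selected pulse from each sweep,
#' aligned to the presynaptic spike time, and averages. For first-pulse
#' (strength/kinetics) analysis only trains at or below `max_frequency`
#' (default 50 Hz) are pooled. The returned trace is baseline-subtracted
#' (mean of the 10 ms preceding the spike) with time 0 at the spike.
#'
#' The response window is cropped 1 ms before the following pulse (when one
#' exists), so the average of the selected response is never contaminated by
#' the next response in the train.
#'
#' @param sweeps list of `syn_sweep`.
#' @param pulse_index which pulse to average (default 1).
#' @param window c(before, after) in ms around the spike (default c(-10, 50)).
#' @param max_frequency exclude sweeps from faster trains, Hz.
#' @return a `syn_trace`; attribute `n_sweeps` gives the number averaged.
#' @export
average_response <- function(sweeps, pulse_index = 1L, window = c(-10, 50),
                             max_frequency = 50) {
  keep <- vapply(sweeps, function(s)
    is.null(s$protocol) || s$protocol$frequency <= max_frequency, logical(1))
  sweeps <- sweeps[keep]
  if (length(sweeps) == 0) stop_invalid("no sweeps to average")
  gaps <- vapply(sweeps, function(s) {
    st <- s$spike_times
    if (pulse_index < length(st)) st[pulse_index + 1L] - st[pulse_index]
    else Inf
  }, numeric(1))
  window[2] <- min(window[2], min(gaps) - 1)
  segs <- lapply(sweeps, function(s) {
    sp <- s$spike_times[pulse_index]
    seg <- trace_window(s$trace, sp + window[1], sp + window[2])
    bl <- trace_window(s$trace, sp - 10, sp)
    seg - mean(bl)
  })
  n <- min(lengths(segs))
  m <- rowMeans(vapply(segs, function(x) x[1:n], numeric(n)))
  out <- new_trace(m, dt = sweeps[[1]]$trace$dt, t0 = window[1])
  attr(out, "n_sweeps") <- length(sweeps)
  out
}

#' Region weights for the PSP fit
#'
#' The rising phase is most heavily weighted, baseline and decay are
#' intermediately weighted, and the presynaptic stimulus window (which often
#' carries crosstalk artifacts) is masked. Boundaries are relative to the
#' spike time.
#'
#' @param rise_weight,base_weight weights for the rising phase and the rest.
#' @param rise_window c(start, end) of the heavily weighted region, ms after
#'   the spike.
#' @param mask_window c(start, end) of the zero-weight stimulus mask, ms.
#' @export
fit_weights <- function(rise_weight = 30, base_weight = 3,
                        rise_window = c(0.5, 6), mask_window = c(-0.5, 0.5)) {
  list(rise_weight = rise_weight, base_weight = base_weight,
       rise_window = rise_window, mask_window = mask_window)
}

#' Fit the double-exponential PSP model to an averaged response
#'
#' Weighted nonlinear least squares of
#' \eqn{y(t) = A (1 - e^{-(t-t_0)/\tau_r})^2 e^{-(t-t_0)/\tau_d}}
#' (zero before \eqn{t_0}), parameterized by the curve peak. Multi-start over
#' onset and decay grids; the best weighted error wins. The weighted RMS
#' error (WRMSE) is normalized by the baseline RMS so the goodness-of-fit
#' threshold is scale-free.
#'
#' @param avg baseline-subtracted `syn_trace` from [average_response()]
#'   (spanning >= 10 ms before and >= 15 ms after the spike).
#' @param spike_time presynaptic max-dV/dt time on the trace's clock
#'   (default 0, matching [average_response()] output).
#' @param weights a [fit_weights()].
#' @param t0_starts,tau_d_starts multi-start grids, ms after spike / ms.
#' @return list of class `psp_fit`: `A` (shape scale), `t0` (foot time, ms),
#'   `tau_r`, `tau_d` (ms), `amplitude` (fitted-curve peak, mV), `latency`
#'   (t0 - spike_time, ms), `rise_time_20_80` (ms), `wrmse`, `fitted`
#'   (`syn_trace`), `success`.
#' @export
fit_psp <- function(avg, spike_time = 0, weights = fit_weights(),
                    t0_starts = c(1, 2, 3, 4), tau_d_starts = c(5, 15, 50)) {
  tt <- trace_times(avg)
  if (spike_time - tt[1] < 10 - 1e-6 || tt[length(tt)] - spike_time < 15 - 0.5)
    stop_invalid("average must span >= 10 ms before and >= 15 ms after spike")
  rel <- tt - spike_time
  w <- rep(weights$base_weight, length(tt))
  w[rel >= weights$rise_window[1] & rel <= weights$rise_window[2]] <-
    weights$rise_weight
  w[rel >= weights$mask_window[1] & rel <= weights$mask_window[2]] <- 0
  bl <- avg$data[rel < weights$mask_window[1]]
  bl_rms <- max(stats::sd(bl), 1e-9)
  y <- avg$data
  model_curve <- function(p) {
    # p = (peak, t0_rel, log tau_r, log tau_d)
    tau_r <- exp(p[3]); tau_d <- exp(p[4])
    pk <- psp_shape_peak(tau_r, tau_d)
    p[1] * psp_shape(rel - p[2], tau_r, tau_d) / pk$max
  }
  resid_fn <- function(p) sqrt(w) * (model_curve(p) - y)
  peak0 <- max(max(y[rel > 0.5 & rel < 20]), 0.01)
  lower <- c(0, 0, log(0.05), log(1))
  upper <- c(Inf, 10, log(20), log(300))
  best <- NULL
  for (t0s in t0_starts) for (tds in tau_d_starts) {
    fit <- tryCatch(
      suppressWarnings(
        minpack.lm::nls.lm(par = c(peak0, t0s, log(1), log(tds)),
                           lower = lower, upper = upper, fn = resid_fn,
                           control = minpack.lm::nls.lm.control(maxiter = 100))),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best))
    stop_invalid("PSP fit failed from all starts")
  p <- best$par
  tau_r <- exp(p[3]); tau_d <- exp(p[4])
  pk <- psp_shape_peak(tau_r, tau_d)
  wrmse <- sqrt(best$deviance / sum(w)) / bl_rms
  structure(list(
    A = p[1] / pk$max, t0 = spike_time + p[2], tau_r = tau_r, tau_d = tau_d,
    amplitude = p[1], latency = p[2],
    rise_time_20_80 = rise_time_20_80(tau_r, tau_d),
    wrmse = wrmse,
    fitted = new_trace(model_curve(p), dt = avg$dt, t0 = avg$t0),
    success = TRUE), class = "psp_fit")
}

#' 20-80% rise time of the double-exponential shape
#'
#' Duration between the 20% and 80% crossings of the peak on the rising
#' phase, for given rise and decay time constants (ms).
#'
#' @param tau_r,tau_d shape time constants, ms.
#' @export
rise_time_20_80 <- function(tau_r, tau_d) {
  pk <- psp_shape_peak(tau_r, tau_d)
  f <- function(frac) {
    stats::uniroot(function(s) psp_shape(s, tau_r, tau_d) - frac * pk$max,
                   lower = 1e-9, upper = pk$s_peak, tol = 1e-10)$root
  }
  f(0.8) - f(0.2)
}

#' @export
print.psp_fit <- function(x, ...) {
  cat(sprintf(paste0("<psp_fit> amplitude %.3g mV, latency %.3g ms, ",
                     "rise(20-80) %.3g ms, tau_d %.3g ms, wrmse %.3g\n"),
              x$amplitude, x$latency, x$rise_time_20_80, x$tau_d, x$wrmse))
  invisible(x)
}

#' Kinetics inclusion filter
#'
#' A fit qualifies for kinetics (latency, rise time) analysis iff its
#' weighted RMS error is strictly below 8.
#'
#' @param fit a `psp_fit`.
#' @param threshold WRMSE cutoff (default 8).
#' @export
kinetics_filter <- function(fit, threshold = 8) {
  fit$wrmse < threshold
}

#' Coefficient of variation of first-pulse amplitudes
#'
#' SD / mean (sample SD, n - 1 denominator); inversely related to release
#' probability.
#'
#' @param amplitudes numeric vector (>= 2 values, nonzero mean).
#' @export
compute_cv <- function(amplitudes) {
  if (length(amplitudes) < 2) stop_invalid("need >= 2 amplitudes for CV")
  m <- mean(amplitudes)
  if (m == 0) stop_invalid("CV undefined: zero mean")
  stats::sd(amplitudes) / m
}

#' EPSP amplitude run-down over the experiment
#'
#' Ordinary least-squares regression of first-pulse amplitude against wall
#' time for sweeps held between -75 and -65 mV, expressed as percent of the
#' initial (intercept) amplitude lost per minute; positive values indicate
#' run-down.
#'
#' @param wall_time_s sweep times, seconds since experiment start.
#' @param amplitude fitted first-pulse amplitudes, mV.
#' @param holding optional holding potentials, mV; rows outside
#'   `holding_range` are dropped.
#' @param holding_range inclusive window, mV (default c(-75, -65)).
#' @return rate in percent per minute.
#' @export
estimate_rundown <- function(wall_time_s, amplitude, holding = NULL,
                             holding_range = c(-75, -65)) {
  if (!is.null(holding)) {
    keep <- holding >= holding_range[1] & holding <= holding_range[2]
    wall_time_s <- wall_time_s[keep]; amplitude <- amplitude[keep]
  }
  if (length(amplitude) < 3)
    stop_invalid("insufficient data: need >= 3 points in the holding window")
  mins <- wall_time_s / 60
  co <- stats::coef(stats::lm(amplitude ~ mins))
  100 * (-co[[2]]) / co[[1]]
}
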