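#' Stimulus protocol for a paired recording
#'
#' Builds the standard induction/recovery train: `n_induction` pulses at
#' `frequency`, a recovery delay inserted after the last induction pulse, then
#' `n_recovery` more pulses at the same frequency. All times are ms from trial
#' start, first pulse at 0.
#'
#' @param frequency pulse rate in Hz (the study set is 10, 20, 50, 100).
#' @param recovery_delay delay between induction and recovery blocks, ms
#'   (study set: 250, 500, 1000, 2000, 4000).
#' @param n_trials number of repeats of the train (default 5).
#' @param n_induction,n_recovery pulse counts (defaults 8 and 4).
#' @param inter_trial_interval seconds between trials (default 15).
#' @return a `stim_protocol` with an explicit `spike_times` vector (ms).
#' @export
make_protocol <- function(frequency, recovery_delay = 250, n_trials = 5L,
                          n_induction = 8L, n_recovery = 4L,
                          inter_trial_interval = 15) {
  if (frequency <= 0) stop_invalid("frequency must be positive")
  if (recovery_delay < 0) stop_invalid("recovery_delay must be >= 0")
  if (n_trials < 1 || n_induction < 1 || n_recovery < 1)
    stop_invalid("all counts must be >= 1")
  ipi <- 1000 / frequency
  ind <- (seq_len(n_induction) - 1L) * ipi
  rec <- ind[n_induction] + recovery_delay + (seq_len(n_recovery) - 1L) * ipi
  structure(list(frequency = frequency, recovery_delay = recovery_delay,
                 n_trials = as.integer(n_trials),
                 n_induction = as.integer(n_induction),
                 n_recovery = as.integer(n_recovery),
                 inter_trial_interval = inter_trial_interval,
                 spike_times = c(ind, rec)),
            class = "stim_protocol")
}

#' Synthetic PSP shape configuration
#'
#' The kernel follows the double-exponential form
#' \eqn{y(t) = A (1 - e^{-(t-t_0)/\tau_r})^2 e^{-(t-t_0)/\tau_d}}. Simulated
#' PSPs are specified by their foot-to-peak rise time (2 ms by default); the
#' rise time constant \eqn{\tau_r} is calibrated numerically from it.
#'
#' @param rise_time foot-to-peak rise time, ms.
#' @param decay_tau decay time constant \eqn{\tau_d}, ms.
#' @param latency_mean,latency_sd Gaussian synaptic latency, ms.
#' @export
psp_config <- function(rise_time = 2, decay_tau = 15,
                       latency_mean = 2, latency_sd = 0.2) {
  stopifnot(rise_time > 0, decay_tau > 0, latency_mean > 0, latency_sd >= 0)
  list(rise_time = rise_time, decay_tau = decay_tau,
       latency_mean = latency_mean, latency_sd = latency_sd)
}

#' Stochastic EPSP amplitude model
#'
#' Per-event amplitudes are the product of a binomial count (stochastic
#' vesicle release) and a normal gain (vesicle size / receptor efficacy),
#' rescaled by a common factor so the distribution mean equals
#' `target_mean_amplitude`.
#'
#' @param binom_n,binom_p binomial release parameters (defaults 24, 0.2).
#' @param gain_mean,gain_sd normal gain parameters (defaults 1, 0.3).
#' @param target_mean_amplitude desired mean amplitude, mV.
#' @export
amplitude_model <- function(binom_n = 24L, binom_p = 0.2,
                            gain_mean = 1, gain_sd = 0.3,
                            target_mean_amplitude = 0.5) {
  stopifnot(binom_n >= 1, binom_p > 0, binom_p <= 1, gain_sd >= 0)
  list(binom_n = as.integer(binom_n), binom_p = binom_p,
       gain_mean = gain_mean, gain_sd = gain_sd,
       target_mean_amplitude = target_mean_amplitude)
}

#' Background noise model
#'
#' Background noise is low-pass filtered Gaussian white noise. Because the
#' reference scale for recording noise is its RMS after exponential
#' deconvolution (population scale ~0.6 mV), the model is parameterized by the
#' target deconvolved RMS; the raw trace is scaled accordingly at generation
#' time.
#'
#' @param deconv_rms target RMS (mV) of the deconvolved (tau = 15 ms) noise.
#' @param lowpass_khz noise bandwidth, kHz.
#' @param deconv_tau deconvolution time constant used for calibration, ms.
#' @export
noise_model <- function(deconv_rms = 0.6, lowpass_khz = 2, deconv_tau = 15) {
  stopifnot(deconv_rms >= 0, lowpass_khz > 0)
  list(deconv_rms = deconv_rms, lowpass_khz = lowpass_khz,
       deconv_tau = deconv_tau)
}

# tau_r such that the kernel's foot-to-peak rise time equals `rise_time`,
# given decay tau_d. Peak occurs at s* = tau_r * log(1 + 2 tau_d / tau_r).
calibrate_tau_r <- function(rise_time, tau_d) {
  f <- function(tr) tr * log1p(2 * tau_d / tr) - rise_time
  stats::uniroot(f, lower = 1e-4, upper = rise_time * 2, tol = 1e-12)$root
}

# unit double-exponential shape; s in ms relative to onset, 0 for s < 0
psp_shape <- function(s, tau_r, tau_d) {
  y <- numeric(length(s))
  p <- s > 0
  y[p] <- (1 - exp(-s[p] / tau_r))^2 * exp(-s[p] / tau_d)
  y
}

psp_shape_peak <- function(tau_r, tau_d) {
  s_peak <- tau_r * log1p(2 * tau_d / tau_r)
  list(s_peak = s_peak, max = psp_shape(s_peak, tau_r, tau_d))
}

#' Peak-normalized PSP kernel on a sampling grid
#'
#' Evaluates the double-exponential PSP shape with onset `onset`, rescaled so
#' its maximum equals `amplitude` exactly, on the grid of `grid` (a
#' `syn_trace` template; only its `dt`, `t0` and length are used).
#'
#' @param amplitude peak amplitude, mV (>= 0; negative values produce an
#'   inverted kernel, used for stochastic amplitude draws).
#' @param config a [psp_config()].
#' @param onset kernel foot time, ms.
#' @param grid a `syn_trace` defining the sampling grid.
#' @return a `syn_trace` of the kernel.
#' @export
psp_kernel <- function(amplitude, config = psp_config(), onset, grid) {
  tmax <- grid$t0 + (length(grid$data) - 1L) * grid$dt
  if (onset < grid$t0 || onset > tmax)
    stop_invalid("onset %.3f ms outside grid [%.3f, %.3f]", onset, grid$t0, tmax)
  tau_r <- calibrate_tau_r(config$rise_time, config$decay_tau)
  pk <- psp_shape_peak(tau_r, config$decay_tau)
  s <- trace_times(grid) - onset
  new_trace(amplitude * psp_shape(s, tau_r, config$decay_tau) / pk$max,
            dt = grid$dt, t0 = grid$t0)
}

#' Draw stochastic EPSP amplitudes
#'
#' Each draw is Binomial(`binom_n`, `binom_p`) x Normal(`gain_mean`,
#' `gain_sd`), multiplied by the deterministic factor
#' `target / (binom_n * binom_p * gain_mean)` so the distribution mean equals
#' the target. Negative products (normal gain below zero) are kept.
#'
#' @param model an [amplitude_model()].
#' @param n_events number of draws.
#' @param seed optional integer seed for a local RNG sub-stream.
#' @return numeric vector of amplitudes, mV.
#' @export
sample_amplitudes <- function(model, n_events, seed = NULL) {
  stopifnot(n_events >= 1)
  scale <- model$target_mean_amplitude /
    (model$binom_n * model$binom_p * model$gain_mean)
  with_seed(seed, {
    k <- stats::rbinom(n_events, model$binom_n, model$binom_p)
    g <- stats::rnorm(n_events, model$gain_mean, model$gain_sd)
    k * g * scale
  })
}

# generate one calibrated noise trace (mV) of n samples
gen_noise <- function(noise, n, dt, seed) {
  if (noise$deconv_rms == 0) return(numeric(n))
  raw <- with_seed(seed, stats::rnorm(n + 2000L))
  raw <- butter_filtfilt(raw, noise$lowpass_khz, dt)[1001:(1000L + n)]
  d <- raw + noise$deconv_tau * centered_diff(raw, dt)
  raw * noise$deconv_rms / sqrt(mean(d^2))
}

#' Synthesize one probed pair
#'
#' Generates the full set of sweeps for one putative connection: background
#' noise plus (for connected pairs) a stochastic PSP kernel per presynaptic
#' pulse, optionally modulated by short-term plasticity. Ground truth records
#' every drawn amplitude and latency.
#'
#' @param protocol a [make_protocol()].
#' @param config a [psp_config()].
#' @param model an [amplitude_model()]; ignored when `connected = FALSE`.
#' @param stp_params optional [stp_params()]; when given, each event's mean
#'   amplitude is scaled by the normalized depletion-model amplitude for that
#'   pulse.
#' @param noise a [noise_model()].
#' @param seed integer seed; every sweep uses an independent sub-stream, so
#'   adding sweeps never perturbs earlier ones.
#' @param connected generate PSPs (`TRUE`) or pure noise (`FALSE`).
#' @param sample_khz sampling rate in kHz (default 50).
#' @param pre_ms,post_ms trace padding before the first and after the last
#'   pulse, ms.
#' @param holding_mv resting/holding potential added to the trace (default -70).
#' @param bias_pa recorded auto-bias current metadata, pA.
#' @return list with `sweeps` (list of `syn_sweep`) and `ground_truth`.
#' @export
synthesize_pair <- function(protocol, config = psp_config(),
                            model = amplitude_model(), stp_params = NULL,
                            noise = noise_model(), seed = 1L,
                            connected = TRUE, sample_khz = 50,
                            pre_ms = 50, post_ms = 150,
                            holding_mv = -70, bias_pa = -95) {
  dt <- 1 / sample_khz
  st <- protocol$spike_times
  n <- round((pre_ms + st[length(st)] + post_ms) / dt) + 1L
  stp_norm <- if (!is.null(stp_params))
    stp_simulate(stp_params, st)$normalized else rep(1, length(st))
  sweeps <- vector("list", protocol$n_trials)
  amps <- lats <- vector("list", protocol$n_trials)
  for (trial in seq_len(protocol$n_trials)) {
    grid <- new_trace(numeric(n), dt = dt, t0 = -pre_ms)
    v <- gen_noise(noise, n, dt, child_seed(seed, 3L * trial))
    a <- l <- numeric(0)
    if (connected) {
      a <- sample_amplitudes(model, length(st),
                             seed = child_seed(seed, 3L * trial + 1L)) * stp_norm
      l <- with_seed(child_seed(seed, 3L * trial + 2L),
                     stats::rnorm(length(st), config$latency_mean,
                                  config$latency_sd))
      for (k in seq_along(st))
        v <- v + psp_kernel(a[k], config, st[k] + l[k], grid)$data
    }
    sweeps[[trial]] <- new_sweep(
      trace = new_trace(v + holding_mv, dt = dt, t0 = -pre_ms),
      spike_times = st, holding_potential = holding_mv,
      bias_current = bias_pa, protocol = protocol,
      wall_time = (trial - 1) * protocol$inter_trial_interval)
    amps[[trial]] <- a; lats[[trial]] <- l
  }
  gt <- list(connected = connected,
             mean_amplitude = if (connected) model$target_mean_amplitude else 0,
             stp_params = stp_params, stp_normalized = stp_norm,
             per_event_amplitudes = unlist(amps),
             per_event_latencies = unlist(lats))
  list(sweeps = sweeps, ground_truth = gt)
}

#' One recorded sweep
#'
#' @param trace postsynaptic `syn_trace` (absolute membrane potential, mV).
#' @param spike_times presynaptic spike times (max-dV/dt), ms.
#' @param holding_potential,bias_current,protocol,wall_time acquisition
#'   metadata.
#' @export
new_sweep <- function(trace, spike_times, holding_potential = -70,
                      bias_current = 0, protocol = NULL, wall_time = 0) {
  structure(list(trace = trace, spike_times = spike_times,
                 holding_potential = holding_potential,
                 bias_current = bias_current, protocol = protocol,
                 wall_time = wall_time),
            class = "syn_sweep")
}

#' Synthesize a pool of unconnected background recordings
#'
#' Heterogeneous-noise sweep sets for classifier training and detection-limit
#' estimation. Noise levels (deconvolved RMS) are drawn log-normally around
#' `rms_mean`.
#'
#' @param n_pairs number of unconnected pairs.
#' @param protocol a [make_protocol()] shared by all pairs.
#' @param rms_mean,rms_sdlog log-normal deconvolved-RMS distribution (mV).
#' @param seed integer seed.
#' @param ... further arguments passed to [synthesize_pair()].
#' @return list of sweep lists (one element per pair), with the drawn RMS as
#'   attribute `deconv_rms` on each.
#' @export
synthesize_background_pool <- function(n_pairs, protocol = make_protocol(50),
                                       rms_mean = 0.6, rms_sdlog = 0.5,
                                       seed = 1L, ...) {
  if (n_pairs == 0) return(list())
  rms <- with_seed(child_seed(seed, 0L),
                   stats::rlnorm(n_pairs, log(rms_mean), rms_sdlog))
  lapply(seq_len(n_pairs), function(i) {
    p <- synthesize_pair(protocol, noise = noise_model(deconv_rms = rms[i]),
                         seed = child_seed(seed, i), connected = FALSE, ...)
    structure(p$sweeps, deconv_rms = rms[i])
  })
}
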