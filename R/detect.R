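# Synapse detection: feature extraction from probed pairs, a probabilistic
# classifier, simulated-EPSP detection-limit estimation, the corrected
# amplitude distribution, and the optogenetic SNR scorer.

#' Extract classification features from a probed pair
#'
#' Deterministic feature vector for one putative connection: parameters and
#' normalized RMS error of the double-exponential fit to the averaged
#' response, plus Kolmogorov-Smirnov p-values comparing per-trial deconvolved
#' peak amplitudes and peak times (measured over a 3 ms window beginning 1 ms
#' after each presynaptic spike) against matched windows tiled over the
#' pre-stimulus background, and the deconvolved background RMS.
#'
#' @param sweeps list of `syn_sweep` (>= 5 required).
#' @param tau deconvolution time constant, ms.
#' @param response_window c(start, length) of the per-trial response window
#'   after each spike, ms (default 1 ms offset, 3 ms long).
#' @param fit_decimate integer decimation factor applied to the averaged
#'   response before curve fitting (speed; default 5, i.e. 10 kHz for 50 kHz
#'   input).
#' @return list of class `pair_features`.
#' @export
extract_features <- function(sweeps, tau = 15, response_window = c(1, 3),
                             fit_decimate = 5L) {
  if (length(sweeps) < 5)
    stop_invalid("insufficient data: >= 5 QC-passed sweeps required")
  avg <- average_response(sweeps, pulse_index = 1L, window = c(-10, 50),
                          max_frequency = Inf)
  if (fit_decimate > 1L) {
    idx <- seq(1L, length(avg$data), by = fit_decimate)
    avg <- new_trace(avg$data[idx], dt = avg$dt * fit_decimate, t0 = avg$t0)
  }
  fit <- fit_psp(avg, spike_time = 0)

  resp_amp <- resp_t <- bg_amp <- bg_t <- numeric(0)
  bg_rms <- numeric(length(sweeps))
  wlen <- response_window[2]
  for (i in seq_along(sweeps)) {
    s <- sweeps[[i]]
    d <- deconvolve(s$trace, tau)
    first <- min(s$spike_times)
    for (sp in s$spike_times) {
      w <- trace_window(d, sp + response_window[1],
                        sp + response_window[1] + wlen)
      j <- which.max(w)
      resp_amp <- c(resp_amp, w[j])
      resp_t <- c(resp_t, (j - 1) * d$dt)
    }
    # matched-length windows tiled over the pre-stimulus baseline
    starts <- seq(d$t0 + 1, first - 1 - wlen, by = wlen)
    for (b0 in starts) {
      w <- trace_window(d, b0, b0 + wlen)
      j <- which.max(w)
      bg_amp <- c(bg_amp, w[j])
      bg_t <- c(bg_t, (j - 1) * d$dt)
    }
    bl <- trace_window(d, first - 10, first - 0.5)
    bg_rms[i] <- sqrt(mean((bl - mean(bl))^2))
  }
  ks_a <- suppressWarnings(stats::ks.test(resp_amp, bg_amp))$p.value
  ks_t <- suppressWarnings(stats::ks.test(resp_t, bg_t))$p.value
  structure(list(amplitude = fit$amplitude, latency = fit$latency,
                 rise_time = fit$rise_time_20_80, tau_d = fit$tau_d,
                 fit_nrmse = fit$wrmse,
                 ks_p_amplitude = ks_a, ks_p_time = ks_t,
                 background_rms = mean(bg_rms)),
            class = "pair_features")
}

# feature list -> one-row data.frame with log-transformed p-values
features_row <- function(f) {
  data.frame(amplitude = f$amplitude, latency = f$latency,
             rise_time = f$rise_time, log_tau_d = log(f$tau_d),
             fit_nrmse = f$fit_nrmse,
             log_ks_p_amplitude = log10(max(f$ks_p_amplitude, 1e-300)),
             log_ks_p_time = log10(max(f$ks_p_time, 1e-300)),
             background_rms = f$background_rms)
}

#' Assemble a feature data frame
#' @param feature_list list of `pair_features`.
#' @export
features_frame <- function(feature_list) {
  do.call(rbind, lapply(feature_list, features_row))
}

#' Train the synapse-detection classifier
#'
#' A margin-based (support vector machine, radial kernel) classifier with
#' probability calibration over the extracted features. Training is seeded so
#' repeated training on the same data gives identical predictions.
#'
#' @param features data frame from [features_frame()].
#' @param connected logical label per row; both classes must be present.
#' @param seed integer seed for the probability-calibration step.
#' @param ... passed to [e1071::svm()].
#' @return classifier handle of class `syn_classifier`.
#' @export
train_classifier <- function(features, connected, seed = 1L, ...) {
  if (length(unique(connected)) < 2)
    stop_invalid("both connected and unconnected examples required")
  y <- factor(connected, levels = c(FALSE, TRUE))
  model <- with_seed(seed,
    e1071::svm(x = as.matrix(features), y = y, probability = TRUE,
               kernel = "radial", scale = TRUE, ...))
  structure(list(model = model, feature_names = colnames(features),
                 seed = seed),
            class = "syn_classifier")
}

#' Predict connection probability
#'
#' @param classifier a `syn_classifier`.
#' @param features a `pair_features`, a list of them, or a data frame from
#'   [features_frame()].
#' @return numeric vector of probabilities in `[0, 1]`.
#' @export
predict_connection <- function(classifier, features) {
  df <- if (inherits(features, "pair_features")) features_row(features)
        else if (is.data.frame(features)) features
        else features_frame(features)
  pred <- stats::predict(classifier$model, as.matrix(df), probability = TRUE)
  as.numeric(attr(pred, "probabilities")[, "TRUE"])
}

#' Minimum detectable amplitude by simulated-EPSP injection
#'
#' For each candidate mean amplitude, simulated EPSPs (stochastic amplitudes
#' scaled to that mean, Gaussian latency, 2 ms rise) are injected at every
#' presynaptic spike time of the background recording; the full feature
#' extraction and classifier are run and the classification probability
#' averaged over `n_repeats` independent injections. The detection limit is
#' the amplitude at which the averaged probability crosses 0.5, interpolated
#' between adjacent grid amplitudes (on log amplitude).
#'
#' @param background list of `syn_sweep` with no true connection.
#' @param classifier a `syn_classifier`.
#' @param config a [psp_config()].
#' @param model an [amplitude_model()] (its target mean is overridden per
#'   grid point).
#' @param amplitudes candidate mean amplitudes, mV (default 14 log-spaced
#'   points from 10 uV to 2 mV).
#' @param n_repeats injections per amplitude (default 8).
#' @param seed integer seed.
#' @param ... passed to [extract_features()].
#' @return list of class `detection_profile`: `amplitude_grid`,
#'   `detection_prob`, `min_detectable_amplitude`, `censored`.
#' @export
min_detectable_amplitude <- function(background, classifier,
                                     config = psp_config(),
                                     model = amplitude_model(),
                                     amplitudes = 10^seq(log10(0.01),
                                                         log10(2), length.out = 14),
                                     n_repeats = 8L, seed = 1L, ...) {
  probs <- vapply(seq_along(amplitudes), function(ai) {
    m <- model; m$target_mean_amplitude <- amplitudes[ai]
    mean(vapply(seq_len(n_repeats), function(rep) {
      injected <- inject_psps(background, config, m,
                              seed = child_seed(seed, ai * 1000L + rep))
      predict_connection(classifier, extract_features(injected, ...))
    }, numeric(1)))
  }, numeric(1))
  cross <- which(probs[-1] >= 0.5 & probs[-length(probs)] < 0.5)
  if (probs[1] >= 0.5) {
    thr <- amplitudes[1]; censored <- FALSE
  } else if (length(cross) == 0) {
    thr <- amplitudes[length(amplitudes)]
    censored <- TRUE
  } else {
    i <- cross[1]
    la <- log10(amplitudes)
    thr <- 10^(la[i] + (0.5 - probs[i]) / (probs[i + 1] - probs[i]) *
                 (la[i + 1] - la[i]))
    censored <- FALSE
  }
  structure(list(amplitude_grid = amplitudes, detection_prob = probs,
                 min_detectable_amplitude = thr, censored = censored),
            class = "detection_profile")
}

#' Inject simulated EPSPs into background sweeps
#'
#' Adds one stochastic PSP kernel per presynaptic spike (amplitudes from the
#' amplitude model, latencies Gaussian) to copies of the background sweeps.
#'
#' @inheritParams min_detectable_amplitude
#' @param seed integer seed.
#' @export
inject_psps <- function(background, config = psp_config(),
                        model = amplitude_model(), seed = 1L) {
  lapply(seq_along(background), function(i) {
    s <- background[[i]]
    st <- s$spike_times
    a <- sample_amplitudes(model, length(st), seed = child_seed(seed, 2L * i))
    l <- with_seed(child_seed(seed, 2L * i + 1L),
                   stats::rnorm(length(st), config$latency_mean,
                                config$latency_sd))
    v <- s$trace$data
    for (k in seq_along(st))
      v <- v + psp_kernel(a[k], config, st[k] + l[k], s$trace)$data
    s$trace <- new_trace(v, dt = s$trace$dt, t0 = s$trace$t0)
    s
  })
}

#' Detection-corrected amplitude distribution
#'
#' Divides the (Gaussian-smoothed) measured amplitude histogram by the
#' cohort-average detection probability at each bin to estimate the
#' underlying distribution of synaptic strengths. Bins where the detection
#' probability falls below `floor` are masked (the correction is unstable as
#' detection probability nears zero).
#'
#' @param measured detected EPSP amplitudes, mV.
#' @param profiles list of `detection_profile`, one per probed pair.
#' @param bin_width histogram bin width, mV.
#' @param sigma_bins Gaussian smoothing SD in bins (default 1).
#' @param floor minimum detection probability for correction (default 0.1).
#' @return list: `breaks`, `mids`, `measured` (smoothed counts),
#'   `detection_prob`, `corrected`, `masked`, `inflation` (corrected total /
#'   measured total - 1 over unmasked bins).
#' @export
corrected_amplitude_distribution <- function(measured, profiles,
                                             bin_width = 0.05,
                                             sigma_bins = 1, floor = 0.1) {
  if (length(measured) == 0 || length(profiles) == 0)
    stop_invalid("measured amplitudes and detection profiles required")
  breaks <- seq(0, (ceiling(max(measured) / bin_width) + 3) * bin_width,
                by = bin_width)
  h <- graphics::hist(measured, breaks = breaks, plot = FALSE)
  smoothed <- gaussian_smooth(h$counts, sigma_bins)
  det <- rowMeans(vapply(profiles, function(p) {
    stats::approx(log10(p$amplitude_grid), p$detection_prob,
                  xout = log10(pmax(h$mids, min(p$amplitude_grid))),
                  rule = 2)$y
  }, numeric(length(h$mids))))
  masked <- det < floor
  corrected <- ifelse(masked, NA_real_, smoothed / pmax(det, floor))
  inflation <- sum(corrected[!masked]) / sum(smoothed[!masked]) - 1
  list(breaks = breaks, mids = h$mids, measured = smoothed,
       detection_prob = det, corrected = corrected, masked = masked,
       inflation = inflation)
}

#' Signal-to-noise scorer for optogenetic mapping responses
#'
#' Implements the deconvolution-based scorer for photostimulation trials:
#' low-pass filter at 1 kHz, baseline subtraction, exponential deconvolution,
#' 30 Hz high-pass, and threshold-crossing peaks above three SDs of the
#' pre-stimulus baseline. Within the 100 ms signal window (5-105 ms after
#' stimulus onset) and the 100 ms noise window (145-45 ms before onset), a
#' 10 ms sub-window maximizing the number of unique trials containing
#' threshold-crossing events is selected; the median across trials of the
#' peak within that sub-window, minus the mean of a 25 ms window preceding
#' both regions, gives the signal and noise values.
#'
#' @param trials list of `syn_trace` spanning at least
#'   `[stim_onset - 170, stim_onset + 105]` ms.
#' @param stim_onset photostimulus onset, ms.
#' @param tau deconvolution time constant, ms (must lie in `[10, 40]`).
#' @param snr_threshold connection-candidate cut on signal / noise
#'   (default 1.5).
#' @return list: `signal`, `noise`, `ratio`, `call` (logical).
#' @export
optogenetic_snr <- function(trials, stim_onset, tau = 15,
                            snr_threshold = 1.5) {
  if (tau < 10 || tau > 40) stop_invalid("tau must be in [10, 40] ms")
  if (length(trials) < 2) stop_invalid("multiple trials required")
  t0 <- trials[[1]]$t0
  tmax <- t0 + (length(trials[[1]]$data) - 1) * trials[[1]]$dt
  if (t0 > stim_onset - 170 || tmax < stim_onset + 105)
    stop_invalid("trials must span [stim - 170, stim + 105] ms")
  proc <- lapply(trials, function(tr) {
    v <- butter_filtfilt(tr$data, 1, tr$dt)
    v <- v - mean(v[trace_times(tr) < stim_onset])
    d <- deconvolve(new_trace(v, dt = tr$dt, t0 = tr$t0), tau)
    d$data <- butter_filtfilt(d$data, 30e-3, d$dt, order = 2L, type = "high")
    d
  })
  sig_win <- c(stim_onset + 5, stim_onset + 105)
  noi_win <- c(stim_onset - 145, stim_onset - 45)
  pre_win <- c(stim_onset - 170, stim_onset - 145)
  # per-trial threshold-crossing peak times
  peak_times <- lapply(proc, function(d) {
    bl <- trace_window(d, noi_win[1], noi_win[2])
    thr <- 3 * stats::sd(bl)
    x <- d$data
    n <- length(x)
    loc <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n] &
                   x[2:(n - 1)] > thr) + 1L
    d$t0 + (loc - 1L) * d$dt
  })
  window_value <- function(win) {
    starts <- seq(win[1], win[2] - 10, by = 1)
    counts <- vapply(starts, function(s0)
      sum(vapply(peak_times, function(pt)
        any(pt >= s0 & pt <= s0 + 10), logical(1))), numeric(1))
    s0 <- starts[which.max(counts)]
    stats::median(vapply(proc, function(d)
      max(trace_window(d, s0, s0 + 10)), numeric(1)))
  }
  pre_mean <- mean(vapply(proc, function(d)
    mean(trace_window(d, pre_win[1], pre_win[2])), numeric(1)))
  signal <- window_value(sig_win) - pre_mean
  noise <- window_value(noi_win) - pre_mean
  ratio <- if (noise > 0) signal / noise else if (signal > 0) Inf else 0
  list(signal = signal, noise = noise, ratio = ratio,
       call = is.finite(ratio) && ratio > snr_threshold || is.infinite(ratio))
}
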