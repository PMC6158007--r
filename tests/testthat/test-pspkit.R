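# Sweep QC, averaging, PSP fitting, CV and run-down

make_clean_pair <- function(seed = 1L, amp = 0.5, n_trials = 5) {
  synthesize_pair(make_protocol(50, 250, n_trials = n_trials),
                  model = amplitude_model(target_mean_amplitude = amp),
                  seed = seed, sample_khz = 20)
}

test_that("sweep QC applies each inclusion rule and reports all failures", {
  pair <- make_clean_pair()
  s <- pair$sweeps[[1]]
  expect_true(qc_sweep(s)$passed)
  s_bias <- s; s_bias$bias_current <- 900
  expect_identical(qc_sweep(s_bias)$reasons, "bias_current")
  s_drift <- s; s_drift$trace$data <- s_drift$trace$data + 6
  expect_identical(qc_sweep(s_drift)$reasons, "baseline_drift")
  s_spk <- s
  i <- trace_index(s_spk$trace, 30)
  s_spk$trace$data[i] <- 10  # suprathreshold excursion
  expect_true("spontaneous_spike" %in% qc_sweep(s_spk)$reasons)
  # a 150 uV rectangular crosstalk artifact in the stimulus window
  s_art <- s
  j <- trace_index(s_art$trace, s$spike_times[1] - 0.3):
    trace_index(s_art$trace, s$spike_times[1] + 0.3)
  s_art$trace$data[j] <- s_art$trace$data[j] + 0.15
  expect_true("artifact" %in% qc_sweep(s_art)$reasons)
  # multiple violations are all reported
  s_both <- s_drift; s_both$bias_current <- 900
  expect_setequal(qc_sweep(s_both)$reasons,
                  c("bias_current", "baseline_drift"))
  # short baseline is a precondition violation
  s_short <- s
  s_short$trace <- new_trace(s$trace$data, dt = s$trace$dt, t0 = -5)
  s_short$spike_times <- s$spike_times
  expect_error(qc_sweep(s_short), "baseline")
})

test_that("connection QC enforces the five-sweep minimum and readmission", {
  pair <- make_clean_pair()
  qc5 <- qc_connection(pair$sweeps)
  expect_true(qc5$qc$passed)
  expect_length(qc5$included, 5)
  qc4 <- qc_connection(pair$sweeps[1:4])
  expect_false(qc4$qc$passed)
  expect_identical(qc4$qc$reasons, "min_sweeps")
  # sweeps depolarized to -55 mV come back only with the STP flag
  mix <- pair$sweeps
  for (i in 4:5) mix[[i]]$trace$data <- mix[[i]]$trace$data + 15
  expect_length(qc_connection(mix)$included, 3)
  expect_length(qc_connection(mix, readmit_depolarized = TRUE)$included, 5)
})

test_that("averaging is linear, permutation-invariant, and cancels noise", {
  pair <- make_clean_pair()
  a1 <- average_response(pair$sweeps)
  a2 <- average_response(rev(pair$sweeps))
  expect_equal(a1$data, a2$data)
  # identical sweeps average to any one of them
  same <- pair$sweeps[c(1, 1, 1)]
  expect_equal(average_response(same)$data,
               average_response(pair$sweeps[1])$data)
  # +x / -x noise realizations around a kernel cancel exactly
  grid <- new_trace(numeric(1201), dt = 0.05, t0 = -10)
  kern <- psp_kernel(0.5, onset = 2, grid = grid)
  noise <- with_seed(3L, rnorm(1201, 0, 0.1))
  sw <- function(x) new_sweep(new_trace(kern$data + x - 70, dt = 0.05,
                                        t0 = -10), spike_times = 0)
  avg <- average_response(list(sw(noise), sw(-noise)))
  expect_equal(avg$data, kern$data, tolerance = 1e-10)
  # 100 Hz sweeps are excluded from first-pulse pooling
  p100 <- synthesize_pair(make_protocol(100, 250, n_trials = 2), seed = 8L,
                          sample_khz = 20)
  avg_mix <- average_response(c(pair$sweeps, p100$sweeps))
  expect_identical(attr(avg_mix, "n_sweeps"), 5L)
  expect_error(average_response(list()), "no sweeps")
})

test_that("noiseless double-exponential fits recover the truth within 1%", {
  for (peak in c(0.1, 0.5)) for (t0 in c(1.5, 3)) {
    for (tr in c(0.5, 2)) for (td in c(10, 30)) {
      tr_true <- raw_eq1_trace(peak, t0, tr, td, dt = 0.05)
      fit <- fit_psp(tr_true, spike_time = 0)
      expect_equal(fit$amplitude, peak, tolerance = 0.01)
      expect_equal(fit$latency, t0, tolerance = 0.01 * t0 + 0.01)
      expect_equal(fit$rise_time_20_80, rise_time_20_80(tr, td),
                   tolerance = 0.01)
    }
  }
})

test_that("latency and rise time are invariant to amplitude rescaling", {
  tr1 <- raw_eq1_trace(0.2, 2, 1, 15, dt = 0.05)
  tr3 <- new_trace(tr1$data * 7, dt = tr1$dt, t0 = tr1$t0)
  f1 <- fit_psp(tr1); f3 <- fit_psp(tr3)
  expect_equal(f1$latency, f3$latency, tolerance = 1e-4)
  expect_equal(f1$rise_time_20_80, f3$rise_time_20_80, tolerance = 1e-4)
  expect_equal(f3$amplitude / f1$amplitude, 7, tolerance = 1e-4)
})

test_that("flat traces yield a near-zero amplitude with near-zero error", {
  flat <- new_trace(numeric(1401), dt = 0.05, t0 = -10)
  fit <- fit_psp(flat)
  expect_lt(fit$amplitude, 1e-6)
  expect_lt(fit$wrmse, 1e-3)
})

test_that("fitted amplitudes recover the population ground truth", {
  # noisy synthetic population; median fit amplitude tracks the median
  # ground-truth mean amplitude within 5%
  amps <- numeric(40); truth <- numeric(40)
  for (i in 1:40) {
    target <- 0.2 + 0.6 * (i - 1) / 39
    pair <- make_clean_pair(seed = 100L + i, amp = target)
    qc <- qc_connection(pair$sweeps)
    fit <- fit_psp(average_response(qc$included))
    amps[i] <- fit$amplitude
    truth[i] <- mean(pair$ground_truth$per_event_amplitudes[
      seq(1, by = 12, length.out = 5)])
  }
  expect_equal(median(amps), median(truth), tolerance = 0.05)
})

test_that("kinetics filter cuts at a weighted error of 8", {
  f <- list(wrmse = 7.9); class(f) <- "psp_fit"
  expect_true(kinetics_filter(f))
  f$wrmse <- 8.0
  expect_false(kinetics_filter(f))
  f$wrmse <- 0
  expect_true(kinetics_filter(f))
})

test_that("coefficient of variation follows SD over mean", {
  expect_equal(compute_cv(c(2, 2, 2)), 0)
  expect_equal(compute_cv(c(1, 2, 3)), 0.5)
  a <- sample_amplitudes(amplitude_model(target_mean_amplitude = 0.4), 1e5,
                         seed = 11)
  expect_equal(compute_cv(a), 0.52122, tolerance = 0.02)
  expect_error(compute_cv(c(1)), ">= 2")
  expect_error(compute_cv(c(-1, 1)), "zero mean")
})

test_that("run-down regression returns percent lost per minute", {
  wt <- seq(0, 1800, by = 45)
  expect_equal(estimate_rundown(wt, rep(0.5, length(wt))), 0)
  amp <- 0.5 * (1 - 0.02 * wt / 60)
  expect_equal(estimate_rundown(wt, amp), 2.0, tolerance = 1e-9)
  # holding filter drops out-of-window sweeps
  hold <- c(rep(-70, 20), rep(-55, length(wt) - 20))
  expect_equal(estimate_rundown(wt, amp, holding = hold), 2.0,
               tolerance = 1e-6)
  expect_error(estimate_rundown(c(0, 60), c(1, 1)), "insufficient")
  # noisy regression: the OLS confidence interval covers the true rate
  set.seed(21)
  true_rate <- 1.5
  wt40 <- seq(0, 40 * 15, length.out = 40)
  amp40 <- 0.5 * (1 - true_rate / 100 * wt40 / 60) + rnorm(40, 0, 0.1 * 0.5)
  fitlm <- lm(amp40 ~ I(wt40 / 60))
  est <- estimate_rundown(wt40, amp40)
  expect_equal(est, 100 * (-coef(fitlm)[[2]]) / coef(fitlm)[[1]])
  # the regression CI (rates implied by the slope CI) covers the truth
  ci_rate <- 100 * (-confint(fitlm)[2, c(2, 1)]) / coef(fitlm)[[1]]
  expect_true(true_rate >= ci_rate[1] && true_rate <= ci_rate[2])
})
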