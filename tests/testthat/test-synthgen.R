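# Synthetic paired-recording generator

test_that("stimulus trains have the induction/delay/recovery structure", {
  p <- make_protocol(50, 250, n_trials = 1)
  expect_equal(p$spike_times,
               c(0, 20, 40, 60, 80, 100, 120, 140, 390, 410, 430, 450))
  # intervals equal 1000/f except the 8 -> 9 gap, which is the delay
  for (f in c(10, 20, 50, 100)) for (d in c(250, 1000, 4000)) {
    st <- make_protocol(f, d, 1)$spike_times
    gaps <- diff(st)
    expect_equal(gaps[-8], rep(1000 / f, 10))
    expect_equal(gaps[8], d)
    expect_true(all(gaps > 0))
  }
  expect_error(make_protocol(0, 250), "frequency")
  expect_error(make_protocol(50, -1), "recovery_delay")
  expect_error(make_protocol(50, 250, n_trials = 0), "counts")
})

test_that("psp kernel is zero before onset and peak-normalized", {
  grid <- new_trace(numeric(5001), dt = 0.02, t0 = 0)
  expect_equal(psp_kernel(0, onset = 10, grid = grid)$data,
               numeric(5001))
  k <- psp_kernel(0.5, psp_config(rise_time = 2, decay_tau = 15),
                  onset = 10, grid = grid)
  expect_lt(abs(max(k$data) - 0.5), 1e-9)
  expect_true(all(k$data[trace_times(k) <= 10] == 0))
  # foot-to-peak rise equals the configured rise time
  expect_equal(trace_times(k)[which.max(k$data)], 12, tolerance = 1e-3)
  expect_error(psp_kernel(0.5, onset = 200, grid = grid), "outside")
})

test_that("kernel peak location matches dense brute-force evaluation", {
  cfg <- psp_config(rise_time = 2, decay_tau = 15)
  tau_r <- synphys:::calibrate_tau_r(cfg$rise_time, cfg$decay_tau)
  s_dense <- seq(0, 20, by = 1e-3)  # 1 us grid
  y <- (1 - exp(-s_dense / tau_r))^2 * exp(-s_dense / cfg$decay_tau)
  s_peak_dense <- s_dense[which.max(y)]
  expect_equal(synphys:::psp_shape_peak(tau_r, cfg$decay_tau)$s_peak,
               s_peak_dense, tolerance = 1e-3)
  grid <- new_trace(numeric(50001), dt = 0.001, t0 = 0)
  k <- psp_kernel(1, cfg, onset = 0, grid = grid)
  expect_equal(trace_times(k)[which.max(k$data)], s_peak_dense,
               tolerance = 2e-3)
})

test_that("stochastic amplitudes have the product-model moments", {
  # degenerate model: every draw is exactly the target
  m0 <- amplitude_model(binom_p = 1, gain_sd = 0,
                        target_mean_amplitude = 0.37)
  expect_equal(sample_amplitudes(m0, 100, seed = 1), rep(0.37, 100))
  # analytic CV for Binom(24, 0.2) x N(1, 0.3): 0.52122
  a <- sample_amplitudes(amplitude_model(target_mean_amplitude = 0.5),
                         1e5, seed = 42)
  expect_equal(mean(a), 0.5, tolerance = 3 * sd(a) / sqrt(1e5) / 0.5)
  expect_equal(sd(a) / mean(a), 0.52122, tolerance = 0.02)
  # negative products exist but are rare (normal gain below zero)
  expect_lt(mean(a < 0), 2e-3)
})

test_that("identical seeds give bit-identical sweeps and ground truth", {
  proto <- make_protocol(50, 250, n_trials = 3)
  p1 <- synthesize_pair(proto, seed = 9L, sample_khz = 20)
  p2 <- synthesize_pair(proto, seed = 9L, sample_khz = 20)
  expect_identical(p1$sweeps[[2]]$trace$data, p2$sweeps[[2]]$trace$data)
  expect_identical(p1$ground_truth, p2$ground_truth)
  # per-sweep sub-streams: adding trials never perturbs earlier sweeps
  proto5 <- make_protocol(50, 250, n_trials = 5)
  p5 <- synthesize_pair(proto5, seed = 9L, sample_khz = 20)
  expect_identical(p1$sweeps[[3]]$trace$data, p5$sweeps[[3]]$trace$data)
})

test_that("noiseless sweeps are the exact superposition of drawn kernels", {
  proto <- make_protocol(50, 250, n_trials = 2)
  cfg <- psp_config()
  p <- synthesize_pair(proto, config = cfg,
                       noise = noise_model(deconv_rms = 0), seed = 4L,
                       sample_khz = 20)
  gt <- p$ground_truth
  st <- proto$spike_times
  for (trial in 1:2) {
    sw <- p$sweeps[[trial]]
    v <- numeric(length(sw$trace$data))
    idx <- (trial - 1) * length(st) + seq_along(st)
    for (k in seq_along(st))
      v <- v + psp_kernel(gt$per_event_amplitudes[idx[k]], cfg,
                          st[k] + gt$per_event_latencies[idx[k]],
                          sw$trace)$data
    expect_equal(sw$trace$data, v + sw$holding_potential, tolerance = 1e-12)
  }
})

test_that("stp-modulated ground truth matches the model simulation", {
  proto <- make_protocol(50, 250, n_trials = 1)
  pars <- stp_params(P0 = 0.30, tau_r0 = 1.26, tau_FDR = 130.6, a_FDR = 0.85)
  p <- synthesize_pair(proto, stp_params = pars,
                       model = amplitude_model(binom_p = 1, gain_sd = 0,
                                               target_mean_amplitude = 0.5),
                       noise = noise_model(deconv_rms = 0), seed = 2L,
                       sample_khz = 20)
  sim <- stp_simulate(pars, proto$spike_times)
  expect_equal(p$ground_truth$stp_normalized, sim$normalized)
  expect_equal(p$ground_truth$per_event_amplitudes / 0.5, sim$normalized)
  # vanishing release probability: no depression
  tiny <- stp_params(P0 = 1e-6, tau_r0 = 1.26, tau_FDR = 130.6, a_FDR = 0)
  sim0 <- stp_simulate(tiny, proto$spike_times)
  expect_equal(sim0$normalized, rep(1, 12), tolerance = 1e-4)
})

test_that("background pool is empty at n = 0 and reproducible", {
  expect_identical(synthesize_background_pool(0), list())
  proto <- make_protocol(50, 250, n_trials = 2)
  b1 <- synthesize_background_pool(3, proto, seed = 5L, sample_khz = 20)
  b2 <- synthesize_background_pool(3, proto, seed = 5L, sample_khz = 20)
  expect_identical(b1[[3]][[1]]$trace$data, b2[[3]][[1]]$trace$data)
  expect_length(b1, 3)
})

test_that("generated noise hits the target deconvolved rms", {
  nm <- noise_model(deconv_rms = 0.6)
  v <- synphys:::gen_noise(nm, 40000L, 0.05, seed = 7L)
  d <- deconvolve(new_trace(v, dt = 0.05), 15)
  expect_equal(sqrt(mean(d$data^2)), 0.6, tolerance = 1e-6)
})
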