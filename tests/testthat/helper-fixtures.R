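# Shared fixtures. The small classifier used by the detect unit tests is
# built lazily once per test run and cached in this environment.

.fixture_cache <- new.env(parent = emptyenv())

detect_protocol <- function() make_protocol(50, 250, n_trials = 5)

# small labeled cohort + trained classifier at 20 kHz (desk scale)
small_classifier <- function() {
  if (!is.null(.fixture_cache$clf)) return(.fixture_cache$clf)
  proto <- detect_protocol()
  n_conn <- 40L; n_unc <- 80L
  amps <- 10^seq(log10(0.05), log10(2), length.out = n_conn)
  rms <- with_seed(1001L, exp(stats::rnorm(n_conn, log(0.6), 0.5)))
  feats <- vector("list", n_conn + n_unc)
  lab <- logical(n_conn + n_unc)
  for (i in seq_len(n_conn)) {
    p <- synthesize_pair(proto,
                         model = amplitude_model(target_mean_amplitude = amps[i]),
                         noise = noise_model(deconv_rms = rms[i]),
                         seed = child_seed(2002L, i), sample_khz = 20)
    feats[[i]] <- extract_features(p$sweeps)
    lab[i] <- TRUE
  }
  bg <- synthesize_background_pool(n_unc, proto, seed = 3003L,
                                   sample_khz = 20)
  for (j in seq_len(n_unc)) {
    feats[[n_conn + j]] <- extract_features(bg[[j]])
  }
  clf <- train_classifier(features_frame(feats), lab, seed = 1L)
  .fixture_cache$clf <- clf
  clf
}

# with_seed / child_seed are internal; expose them to helpers and tests
with_seed <- synphys:::with_seed
child_seed <- synphys:::child_seed
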