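# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths for the quantities they check.

# Forward-Euler integration of the depletion + use-dependent-replenishment
# ODEs at step h (ms); brute-force oracle for the closed-form event-driven
# simulation.
euler_stp <- function(params, spike_times, h = 0.001) {
  tr0 <- params$tau_r0 * 1000
  n <- 1; tr <- tr0
  w <- numeric(length(spike_times))
  t <- spike_times[1]; k <- 1
  while (k <= length(spike_times)) {
    while (k <= length(spike_times) && t >= spike_times[k] - h / 2) {
      w[k] <- params$A * n * params$P0
      n <- n * (1 - params$P0)
      tr <- tr * (1 - params$a_FDR)
      k <- k + 1
    }
    if (k > length(spike_times)) break
    n <- n + h * (1 - n) / tr
    tr <- tr + h * (tr0 - tr) / params$tau_FDR
    t <- t + h
  }
  list(w = w, normalized = w / w[1])
}

# Fixed-recovery (a_FDR = 0) depletion recursion, independent of the
# closed-form propagation: n_{k+1} = 1 - (1 - n_k (1 - P0)) exp(-delta/tau).
fixed_tau_train <- function(P0, tau_r0_s, delta_ms, n_pulses) {
  tau <- tau_r0_s * 1000
  n <- numeric(n_pulses)
  n[1] <- 1
  for (k in 2:n_pulses)
    n[k] <- 1 - (1 - n[k - 1] * (1 - P0)) * exp(-delta_ms / tau)
  n
}

# Beta quantile by numerical CDF inversion: integrate the density with
# integrate() and invert with uniroot (never calls qbeta/pbeta).
beta_quantile_oracle <- function(q, shape1, shape2) {
  dens <- function(x) stats::dbeta(x, shape1, shape2)
  cdf <- function(x) stats::integrate(dens, 0, x, rel.tol = 1e-12)$value
  stats::uniroot(function(x) cdf(x) - q, interval = c(1e-12, 1 - 1e-12),
                 tol = 1e-12)$root
}

# Two-sided Fisher exact p by full enumeration of tables with fixed margins
# (probability-mass method).
fisher_enum <- function(k1, n1, k2, n2) {
  m <- k1 + k2
  probs <- vapply(0:m, function(x) {
    if (x > n1 || (m - x) > n2) return(NA_real_)
    stats::dhyper(x, n1, n2, m)
  }, numeric(1))
  obs <- probs[k1 + 1]
  sum(probs[!is.na(probs) & probs <= obs * (1 + 1e-7)], na.rm = TRUE)
}

# Eq.-1 trace built directly from raw shape parameters (tau_r given, no
# rise-time calibration), for fit recovery tests.
raw_eq1_trace <- function(peak, t0, tau_r, tau_d, dt = 0.02,
                          span = c(-10, 60)) {
  tt <- seq(span[1], span[2], by = dt)
  s <- tt - t0
  y <- numeric(length(s))
  p <- s > 0
  y[p] <- (1 - exp(-s[p] / tau_r))^2 * exp(-s[p] / tau_d)
  new_trace(peak * y / max(y), dt = dt, t0 = span[1])
}
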