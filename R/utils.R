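# Internal helpers: seeded sub-streams and filtering.

# Derive a child seed from a base seed and a counter. Linear-congruential
# mixing keeps every derived seed a valid 32-bit integer and guarantees that
# adding later sub-streams never perturbs earlier ones.
child_seed <- function(seed, k) {
  s <- (as.double(seed) %% 2147483629)
  as.integer((s * 48271 + 7919 * as.double(k) + 1) %% 2147483629)
}

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

# Zero-phase Butterworth filter. `cutoff_khz` in kHz, `dt` in ms; `type`
# "low" or "high". Returns the filtered vector.
butter_filtfilt <- function(x, cutoff_khz, dt, order = 4L, type = "low") {
  nyquist_khz <- 1 / (2 * dt)
  w <- cutoff_khz / nyquist_khz
  stopifnot(w > 0, w < 1)
  bf <- signal::butter(order, w, type = type)
  as.numeric(signal::filtfilt(bf, x))
}

# Gaussian smoothing of a histogram-count vector with sd `sigma` (in bins).
# Each bin's mass is redistributed with a kernel renormalized over in-range
# bins, so the total count is conserved exactly.
gaussian_smooth <- function(x, sigma = 1) {
  if (sigma <= 0) return(x)
  n <- length(x)
  half <- max(1L, ceiling(4 * sigma))
  out <- numeric(n)
  for (j in seq_len(n)) {
    if (x[j] == 0) next
    lo <- max(1L, j - half); hi <- min(n, j + half)
    k <- stats::dnorm((lo:hi) - j, sd = sigma)
    out[lo:hi] <- out[lo:hi] + x[j] * k / sum(k)
  }
  out
}

stop_invalid <- function(...) stop(sprintf(...), call. = FALSE)
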