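# Short-term depression with use-dependent replenishment.
#
# State: vesicle fraction n and recovery time constant tau_r. Between spikes
#   dn/dt      = (1 - n) / tau_r(t)
#   dtau_r/dt  = (tau_r0 - tau_r) / tau_FDR
# and at each presynaptic spike t_k the response w_k = A * n * P0 is read out
# with the pre-spike state, then
#   n     <- n * (1 - P0)
#   tau_r <- tau_r * (1 - a_FDR).
# Both inter-spike updates have closed forms (tau_r relaxes exponentially;
# 1 - n decays by exp(-I) with I = integral dt / tau_r(t), available
# analytically), so the simulation is exact event-driven.

#' Short-term plasticity parameters
#'
#' @param P0 release probability, in (0, 1).
#' @param tau_r0 baseline vesicle-recovery time constant, seconds.
#' @param tau_FDR time constant of use-dependent replenishment, ms.
#' @param a_FDR per-spike fractional reduction of the recovery time constant,
#'   in (0, 1).
#' @param A connection strength scale, mV (default 1; drops out of
#'   normalized amplitudes).
#' @param se optional named vector of standard errors (filled in by
#'   [stp_fit()]).
#' @export
stp_params <- function(P0, tau_r0, tau_FDR, a_FDR, A = 1, se = NULL) {
  stopifnot(P0 > 0, P0 < 1, tau_r0 > 0, tau_FDR > 0, a_FDR >= 0, a_FDR < 1,
            A > 0)
  structure(list(P0 = P0, tau_r0 = tau_r0, tau_FDR = tau_FDR, a_FDR = a_FDR,
                 A = A, se = se),
            class = "stp_params")
}

#' @export
print.stp_params <- function(x, ...) {
  fmt <- function(nm, v, unit) {
    s <- if (!is.null(x$se) && nm %in% names(x$se))
      sprintf(" ± %.3g", x$se[[nm]]) else ""
    sprintf("  %-7s %.4g%s %s\n", nm, v, s, unit)
  }
  cat("<stp_params>\n", fmt("P0", x$P0, ""), fmt("tau_r0", x$tau_r0, "s"),
      fmt("tau_FDR", x$tau_FDR, "ms"), fmt("a_FDR", x$a_FDR, ""), sep = "")
  invisible(x)
}

# integral_0^T dt / (a + b exp(-t/c)), written to avoid overflow for T >> c
stable_int <- function(T, a, b, c) {
  if (abs(b) < 1e-12 * a) return(T / a)
  T / a + (c / a) * (log(a + b * exp(-T / c)) - log(a + b))
}

#' Simulate the depletion + use-dependent replenishment model
#'
#' Event-driven simulation with exact closed-form propagation between spikes.
#'
#' @param params an [stp_params()].
#' @param spike_times strictly increasing spike times, ms.
#' @return list with `w` (per-spike amplitudes, mV), `normalized`
#'   (`w / w[1]`), and the pre-spike state trajectories `n`, `tau_r` (ms).
#' @export
stp_simulate <- function(params, spike_times) {
  if (length(spike_times) == 0) stop_invalid("no spike times")
  if (any(diff(spike_times) <= 0))
    stop_invalid("spike times must be strictly increasing")
  tr0 <- params$tau_r0 * 1000  # ms
  c_fdr <- params$tau_FDR
  n <- 1; tr <- tr0
  ns <- trs <- w <- numeric(length(spike_times))
  for (k in seq_along(spike_times)) {
    if (k > 1) {
      dT <- spike_times[k] - spike_times[k - 1]
      b <- tr - tr0
      I <- stable_int(dT, tr0, b, c_fdr)
      n <- 1 - (1 - n) * exp(-I)
      tr <- tr0 + b * exp(-dT / c_fdr)
    }
    ns[k] <- n; trs[k] <- tr
    w[k] <- params$A * n * params$P0
    n <- n * (1 - params$P0)
    tr <- tr * (1 - params$a_FDR)
  }
  list(w = w, normalized = w / w[1], n = ns, tau_r = trs)
}

#' Fit the STP model to normalized amplitude curves
#'
#' Joint nonlinear least squares of the four dynamic parameters over several
#' stimulus conditions (frequencies and recovery delays). Residuals are
#' unweighted across curves; amplitudes are fit in normalized form so the
#' scale A drops out. Standard errors come from the covariance of the
#' least-squares solution; the coefficient of determination r-squared is
#' computed over the concatenated curves.
#'
#' @param curves list of conditions, each a list with `spike_times` (ms) and
#'   `normalized` (per-pulse amplitudes relative to pulse 1).
#' @param init optional [stp_params()] initial guess; when `NULL` a
#'   multi-start over a 3 x 3 grid of (P0, tau_r0) is used.
#' @param lower,upper parameter bounds, order (P0, tau_r0 s, tau_FDR ms,
#'   a_FDR).
#' @param multi_start use the start grid even when `init` is given.
#' @return an [stp_params()] with `se`, plus attributes `r_squared`,
#'   `rss`, `fitted` (list of fitted normalized curves) and `unreliable_se`
#'   (flag for near-singular covariance).
#' @export
stp_fit <- function(curves, init = NULL,
                    lower = c(0.01, 0.05, 10, 0.01),
                    upper = c(0.99, 20, 5000, 0.99),
                    multi_start = is.null(init)) {
  if (length(curves) < 2)
    stop_invalid("need >= 2 stimulus conditions for identifiability")
  obs <- lapply(curves, function(cv) cv$normalized)
  resid_fn <- function(p) {
    unlist(lapply(seq_along(curves), function(i) {
      prm <- list(P0 = p[1], tau_r0 = p[2], tau_FDR = p[3], a_FDR = p[4],
                  A = 1)
      stp_simulate(prm, curves[[i]]$spike_times)$normalized - obs[[i]]
    }))
  }
  starts <- if (multi_start) {
    g <- expand.grid(P0 = c(0.1, 0.3, 0.6), tau_r0 = c(0.3, 1, 5))
    lapply(seq_len(nrow(g)), function(i) c(g$P0[i], g$tau_r0[i], 200, 0.5))
  } else list()
  if (!is.null(init))
    starts <- c(list(c(init$P0, init$tau_r0, init$tau_FDR, init$a_FDR)),
                starts)
  best <- NULL
  for (s0 in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = s0, lower = lower, upper = upper,
                         fn = resid_fn,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best))
    stop_invalid("STP fit failed to converge from all starts")
  p <- best$par
  y <- unlist(obs)
  rss <- best$deviance
  r2 <- 1 - rss / sum((y - mean(y))^2)
  dof <- length(y) - 4L
  se <- rep(NA_real_, 4)
  unreliable <- TRUE
  hs <- tryCatch(solve(best$hessian), error = function(e) NULL)
  if (!is.null(hs) && dof > 0) {
    v <- diag(hs) * rss / dof
    if (all(is.finite(v)) && all(v >= 0)) {
      se <- sqrt(v)
      unreliable <- kappa(best$hessian) > 1e10
    }
  }
  names(se) <- c("P0", "tau_r0", "tau_FDR", "a_FDR")
  out <- stp_params(p[1], p[2], p[3], p[4], se = se)
  attr(out, "r_squared") <- r2
  attr(out, "rss") <- rss
  attr(out, "unreliable_se") <- unreliable
  attr(out, "at_bounds") <- any(abs(p - lower) < 1e-8 | abs(p - upper) < 1e-8)
  attr(out, "fitted") <- lapply(curves, function(cv)
    stp_simulate(out, cv$spike_times)$normalized)
  out
}

#' Z-score for comparing two fitted parameters
#'
#' \eqn{Z = |X_1 - X_2| / \sqrt{SE_1^2 + SE_2^2}}.
#'
#' @param x1,se1 first parameter estimate and its standard error.
#' @param x2,se2 second parameter estimate and its standard error.
#' @export
param_zscore <- function(x1, se1, x2, se2) {
  if (se1 <= 0 || se2 <= 0) stop_invalid("standard errors must be positive")
  abs(x1 - x2) / sqrt(se1^2 + se2^2)
}

#' Fixed-recovery steady-state depression (a_FDR = 0 closed form)
#'
#' For a periodic train at interval `delta_ms` with constant recovery time
#' constant `tau_r0`, the normalized steady-state amplitude is
#' \eqn{(1 - e^{-\Delta/\tau_{r0}}) / (1 - (1 - P_0) e^{-\Delta/\tau_{r0}})}.
#'
#' @param P0 release probability.
#' @param tau_r0 recovery time constant, seconds.
#' @param delta_ms inter-spike interval, ms.
#' @export
stp_steady_state <- function(P0, tau_r0, delta_ms) {
  e <- exp(-delta_ms / (tau_r0 * 1000))
  (1 - e) / (1 - (1 - P0) * e)
}
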