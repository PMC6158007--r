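# Connectivity statistics: binomial connection probability with Jeffreys
# intervals, distance-binned profiles, Fisher exact comparisons, and the
# optogenetic false-negative correction.

#' Connection probability with 95% Jeffreys interval
#'
#' Point estimate k / n with the Bayesian Jeffreys interval: 2.5% and 97.5%
#' quantiles of Beta(k + 1/2, n - k + 1/2). Boundary convention: the lower
#' limit is 0 when k = 0 and the upper limit is 1 when k = n.
#'
#' @param k connections found.
#' @param n pairs probed (>= 1).
#' @return list: `p` (proportion), `ci95` (length-2 vector), `k`, `n`,
#'   `percent` (100 p rounded to 1 decimal).
#' @export
connection_probability <- function(k, n) {
  if (n < 1) stop_invalid("n must be >= 1")
  if (k < 0 || k > n) stop_invalid("k must satisfy 0 <= k <= n")
  lo <- if (k == 0) 0 else stats::qbeta(0.025, k + 0.5, n - k + 0.5)
  hi <- if (k == n) 1 else stats::qbeta(0.975, k + 0.5, n - k + 0.5)
  p <- k / n
  list(p = p, ci95 = c(lo, hi), k = k, n = n, percent = round(100 * p, 1))
}

#' Distance-binned connectivity profile
#'
#' Half-open 40 um bins `[i w, (i+1) w)` starting at zero, each with its
#' connection probability and Jeffreys interval.
#'
#' @param distance_um intersomatic distances (3D Euclidean), um.
#' @param connected logical per pair.
#' @param bin_width bin width, um (default 40).
#' @return data frame: `bin_lo`, `bin_hi`, `n`, `k`, `p`, `ci_lo`, `ci_hi`.
#' @export
distance_profile <- function(distance_um, connected, bin_width = 40) {
  stopifnot(length(distance_um) == length(connected))
  if (length(distance_um) == 0)
    return(data.frame(bin_lo = numeric(0), bin_hi = numeric(0),
                      n = integer(0), k = integer(0), p = numeric(0),
                      ci_lo = numeric(0), ci_hi = numeric(0)))
  if (any(distance_um < 0)) stop_invalid("distances must be >= 0")
  bin <- floor(distance_um / bin_width)
  out <- do.call(rbind, lapply(sort(unique(bin)), function(b) {
    in_bin <- bin == b
    cp <- connection_probability(sum(connected[in_bin]), sum(in_bin))
    data.frame(bin_lo = b * bin_width, bin_hi = (b + 1) * bin_width,
               n = cp$n, k = cp$k, p = cp$p,
               ci_lo = cp$ci95[1], ci_hi = cp$ci95[2])
  }))
  rownames(out) <- NULL
  out
}

#' Compare two connectivity rates (Fisher exact test)
#'
#' Two-sided exact p-value for the 2 x 2 table (connected, unconnected) by
#' the conventional probability-mass method.
#'
#' @param k1,n1 connections and pairs probed in group 1.
#' @param k2,n2 connections and pairs probed in group 2.
#' @return the two-sided p-value.
#' @export
compare_connectivity <- function(k1, n1, k2, n2) {
  if (n1 < 1 || n2 < 1) stop_invalid("both groups need n >= 1")
  tab <- matrix(c(k1, n1 - k1, k2, n2 - k2), nrow = 2)
  stats::fisher.test(tab, alternative = "two.sided")$p.value
}

#' Pairwise Fisher comparisons with optional Bonferroni adjustment
#'
#' @param counts data frame with columns `group`, `k`, `n`.
#' @param adjust apply Bonferroni correction (default TRUE).
#' @return data frame of group pairs with raw and adjusted p-values.
#' @export
pairwise_connectivity <- function(counts, adjust = TRUE) {
  idx <- utils::combn(nrow(counts), 2)
  out <- data.frame(
    group1 = counts$group[idx[1, ]], group2 = counts$group[idx[2, ]],
    p = apply(idx, 2, function(ij)
      compare_connectivity(counts$k[ij[1]], counts$n[ij[1]],
                           counts$k[ij[2]], counts$n[ij[2]])))
  if (adjust) out$p_adj <- stats::p.adjust(out$p, method = "bonferroni")
  out
}

#' Optogenetic false-negative rate
#'
#' Expected rate of connections missed because the presynaptic cell failed
#' to spike under photostimulation, assuming connectivity independent of
#' photosensitivity: `(1 - photosensitivity) * prior_p`.
#'
#' @param photosensitivity fraction of cells reliably driven to spike, in
#'   `[0, 1]`.
#' @param prior_p prior connection probability, in `[0, 1]`.
#' @export
optogenetic_false_negative <- function(photosensitivity, prior_p) {
  if (photosensitivity < 0 || photosensitivity > 1 ||
      prior_p < 0 || prior_p > 1)
    stop_invalid("both arguments must lie in [0, 1]")
  (1 - photosensitivity) * prior_p
}
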