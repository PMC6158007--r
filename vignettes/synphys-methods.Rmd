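---
title: "Models and methods behind synphys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind synphys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synphys)
```

`synphys` implements the analysis chain used to characterize synaptic
connectivity and short-term plasticity (STP) from multipatch (paired
whole-cell) recordings: synthetic paired-recording generation with known
ground truth, sweep quality control and spike-aligned averaging, PSP curve
fitting, exponential deconvolution, an event-driven vesicle-depletion model
with use-dependent replenishment, a synapse-detection classifier with
simulated-EPSP sensitivity analysis, and binomial connectivity statistics.
This vignette explains the models, the tunable parameters, and the design
choices where the design was genuinely open.

Units are millivolts and milliseconds throughout; recovery time constants of
the STP model are in seconds and replenishment time constants in
milliseconds, matching the conventions their magnitudes make natural.

## The PSP shape and its fit

An excitatory postsynaptic potential (EPSP) is modeled as the
double-exponential

$$y(t) = A\,(1 - e^{-(t-t_0)/\tau_r})^2\, e^{-(t-t_0)/\tau_d}, \qquad t > t_0,$$

zero before the foot time $t_0$. The peak occurs at
$s^\* = \tau_r \log(1 + 2\tau_d/\tau_r)$ after the foot, which gives a
closed-form peak value; `psp_kernel()` rescales the shape so its maximum
equals the requested amplitude exactly. Because simulated EPSPs are
specified by their foot-to-peak rise time (2 ms by default) rather than
$\tau_r$, the kernel calibrates $\tau_r$ numerically from
$\tau_r \log(1 + 2\tau_d/\tau_r) = t_\mathrm{rise}$.

`fit_psp()` fits this shape to a spike-aligned average by
Levenberg–Marquardt least squares (minpack.lm), parameterized by the curve
peak and with $\tau_r, \tau_d$ on log scale. The residual is
region-weighted: weight 30 on the rising phase (0.5–6 ms after the spike),
3 on baseline and decay, and 0 on the stimulus window
($\pm$0.5 ms around the spike), which often carries crosstalk artifacts in
real rigs. The exact weights are exposed through `fit_weights()`; only
their ordering (rise $\gg$ baseline/decay $>$ mask) is meaningful, and fits
are insensitive to factor-of-two changes. A multi-start grid over onset
(1–4 ms) and decay (5, 15, 50 ms) guards against local minima.

The weighted RMS error (WRMSE) is normalized by the baseline RMS of the
average, making it scale-free: a perfect fit to a noisy average gives WRMSE
near 1. Connections enter kinetics summaries only when WRMSE < 8
(`kinetics_filter()`); an absolute cut in millivolts would be meaningless
across noise levels, so the noise-normalized convention is used here and is
the one deliberate reinterpretation of an otherwise unit-less published
threshold.

First-pulse averages pool trains at or below 50 Hz and are cropped 1 ms
before the second pulse of the train; without the crop, the 20 ms
inter-pulse interval at 50 Hz lets the next response contaminate the fit
(the decay constant inflates severely on otherwise clean data).

## Exponential deconvolution

Temporal summation within trains is removed by the exponential
deconvolution

$$D(t) = V(t) + \tau\, \frac{dV}{dt}, \qquad \tau = 15\ \mathrm{ms},$$

which inverts first-order membrane filtering with time constant $\tau$. The
derivative uses centered finite differences by default; a backward
difference form (`method = "recursive"`) is the exact discrete inverse of
`reconvolve()` and round-trips bit-stably.

`train_amplitudes()` averages the sweeps, deconvolves, low-pass filters
(zero-phase 4th-order Butterworth, 1 kHz — the filter family and cutoff are
free choices; normalized amplitudes change negligibly between 0.5 and
3 kHz), and measures each pulse in a window starting 1 ms after the spike
and ending at half the inter-pulse interval, capped at 15 ms. Each peak is
taken relative to the local pre-pulse baseline (mean of the preceding
1 ms). This local referencing matters: when the true membrane time constant
(say 30 ms) differs from the fixed $\tau$, each PSP leaves a residual slow
tail after deconvolution, and at 100 Hz those tails stack under later
pulses. Referencing each peak to its own pre-pulse level removes the
stacked offset; on the standard benchmark (noiseless 100 Hz train, 30 ms
decay, $\tau$ = 15 ms) the maximum normalized-amplitude error is about
0.7%, within the ≤3% bound the fixed-$\tau$ approach claims, while absolute
peak measurement cannot get below about 6% at any cutoff.

## Short-term plasticity model

Synaptic depression is modeled as vesicle depletion with use-dependent
replenishment. The response to spike $k$ is $w_k = A\,n\,P_0$ with $n$ the
available vesicle fraction and $P_0$ the release probability. Between
spikes

$$\frac{dn}{dt} = \frac{1-n}{\tau_r(t)}, \qquad
  \frac{d\tau_r}{dt} = \frac{\tau_{r0} - \tau_r}{\tau_{FDR}},$$

and at each spike, after the readout, $n \leftarrow n(1 - P_0)$ and
$\tau_r \leftarrow \tau_r (1 - a_{FDR})$. Reading out *before* the update
reflects that the PSP is proportional to the vesicles released by that
spike. Both inter-spike updates have closed forms — $\tau_r$ relaxes
exponentially, and $1 - n$ decays by $e^{-I}$ with
$I = \int dt/\tau_r(t)$ available analytically — so `stp_simulate()` is
exact event-driven, with a 1 µs forward-Euler integrator kept in the test
suite as an independent oracle. With $a_{FDR} = 0$ the model reduces to
classical fixed-recovery depletion, whose periodic-train steady state
$(1 - e^{-\Delta/\tau_{r0}})/(1 - (1-P_0)e^{-\Delta/\tau_{r0}})$
(`stp_steady_state()`) is checked to $10^{-8}$.

`stp_fit()` minimizes the summed squared residuals of pulse-1-normalized
amplitudes jointly over all supplied stimulus conditions (the scale $A$
drops out), unweighted across curves, from a 3×3 multi-start grid over
$(P_0, \tau_{r0})$ with bounds $P_0 \in [0.01, 0.99]$,
$\tau_{r0} \in [0.05, 20]$ s, $\tau_{FDR} \in [10, 5000]$ ms,
$a_{FDR} \in [0.01, 0.99]$. Standard errors come from the covariance of
the least-squares solution; a near-singular Hessian or a solution at the
bounds is flagged rather than silently returned. Identifiability requires
at least two stimulus conditions; in practice four frequencies (10, 20, 50,
100 Hz) plus five 50 Hz recovery delays (250–4000 ms) recover $P_0$ to
within a few percent in noiseless data and with bias below 0.02 under
amplitude noise of SD 0.05. Group differences in fitted parameters are
compared with `param_zscore()`,
$Z = |X_1 - X_2|/\sqrt{SE_1^2 + SE_2^2}$.

## The synthetic-data generator

The generator defines the study conditions under which everything else is
tested:

* **Stimuli** — trains of 8 induction pulses at 10, 20, 50, or 100 Hz, a
  recovery delay (250–4000 ms) inserted between the 8th and 9th pulses,
  then 4 recovery pulses; 5 trials per condition at a 15 s inter-trial
  interval. The 8→9 interval *equals* the recovery delay.
* **Amplitudes** — each event draws
  $\mathrm{Binomial}(n{=}24, p{=}0.2) \times \mathcal{N}(1, 0.3)$,
  mimicking stochastic vesicle release times vesicle-size/receptor gain,
  scaled deterministically so the distribution mean equals the target
  (analytic CV 0.521). Negative products (gain below zero, about 0.04% of
  draws) are kept, as the product model implies.
* **Kinetics** — 2 ms foot-to-peak rise, configurable decay (15 ms
  default), latency $\mathcal{N}(2\ \mathrm{ms}, 0.2\ \mathrm{ms})$.
* **Noise** — recording noise is characterized in the literature by its
  RMS *after* deconvolution (population scale ~0.6 mV), not its raw
  spectrum. The noise model is therefore parameterized by target
  deconvolved RMS: low-pass-filtered (2 kHz) Gaussian white noise is scaled
  so `deconvolve(noise, 15)` has exactly that RMS. The spectrum itself is
  a configurable guess; nothing downstream depends on it beyond the
  deconvolved scale.
* **STP** — when STP parameters are supplied, each event's *mean*
  amplitude is scaled by the normalized depletion-model amplitude for that
  pulse, keeping the binomial-times-normal shape (the simplest composition
  consistent with both the amplitude and the STP models).
* **Determinism** — every sweep draws from its own counter-derived
  sub-stream of the master seed, so identical seeds give bit-identical
  cohorts and adding sweeps never perturbs earlier ones.

Default sampling is 50 kHz; the classifier and detection-limit test suites
run at 20 kHz, which resolves the 2 ms rise with 40 samples and keeps the
suites at desk scale. What the generator does *not* emulate: active
membrane dynamics, spontaneous synaptic events, crosstalk artifacts (except
as rectangles injected directly in QC tests), electrode drift, and
synapse-to-synapse variability in CV (the release-statistics parameters are
fixed). Passing tests therefore demonstrate correctness of the analysis
chain under the stated model, not robustness to every pathology of real
recordings.

## Sweep quality control

`qc_sweep()` applies, in order, and reports *all* failures: auto-bias
current below 800 pA; baseline (10 ms before stimulation) within ±5 mV of
the target holding potential (−70 mV); baseline mean within 3 SD of the
across-sweep baseline mean; no suprathreshold excursions above −20 mV
(spontaneous spikes — unambiguous at −70 mV holding); stimulus-window
artifact below 30 µV. The artifact statistic compares the stimulus-window
mean against a quadratic trend extrapolated from the preceding 3 ms, so
smooth PSP tails from earlier pulses in a train do not register while
fast crosstalk transients do. `qc_connection()` requires five surviving
sweeps and can re-admit sweeps held at −55 ± 5 mV for STP analysis.

## Synapse detection and its sensitivity

`extract_features()` produces a deterministic feature vector per probed
pair: the fit parameters and normalized RMS error of the averaged-response
fit, Kolmogorov–Smirnov p-values comparing per-trial deconvolved peak
amplitudes and peak times (3 ms window starting 1 ms after each spike)
against matched 3 ms windows tiled over the pre-stimulus background, and
the deconvolved background RMS. Using matched window lengths makes the
null distribution of the KS p-values uniform, which the tests verify by
simulation. The classifier behind `train_classifier()` is a margin-based
(RBF-kernel SVM, e1071) model with seeded probability calibration; the
feature set, not the classifier family, carries the scientific content,
and the backend is pluggable.

`min_detectable_amplitude()` estimates each pair's detection limit by
injecting simulated EPSPs — one per presynaptic spike, stochastic
amplitudes scaled to a candidate mean, Gaussian latencies — into the pair's
background recording, running the full feature-plus-classifier pipeline,
and averaging the classification probability over 8 independent injections.
The limit is the amplitude at which this averaged probability crosses 0.5,
interpolated linearly against log amplitude over a default grid of 14
log-spaced points from 10 µV to 2 mV. The background recording is held
fixed across repeats (it is the datum an experimenter actually has); only
the PSP draws vary, seeded. Profiles that never reach 0.5 are returned
censored at the grid maximum rather than extrapolated.

`corrected_amplitude_distribution()` divides the Gaussian-smoothed
(σ = 1 bin, mass-conserving at the edges) histogram of detected amplitudes
by the cohort-average detection probability per bin to estimate the
underlying strength distribution; bins with detection probability below 0.1
are masked because the correction is unstable as detection probability
nears zero. The round-trip property — thin a known synthetic population
through per-pair detection curves, correct, recover the total within 15% —
is part of the acceptance suite.

`optogenetic_snr()` scores photostimulation trials: 1 kHz low-pass,
baseline subtraction, deconvolution (τ between 10 and 40 ms), 30 Hz
high-pass, threshold-crossing peaks above 3 SD of the pre-stimulus
baseline; within the 100 ms signal (5–105 ms post-stimulus) and noise
(145–45 ms pre-stimulus) windows, the 10 ms sub-window maximizing the
number of unique trials with threshold crossings is selected, and the
median peak within it, minus the mean of the 25 ms window preceding both
regions, gives the signal and noise values. A ratio above 1.5 marks a
connection candidate. The expected false-negative rate from incomplete
photosensitivity is `(1 - photosensitivity) * prior_p`
(`optogenetic_false_negative()`).

## Connectivity statistics

`connection_probability()` reports $k/n$ with the 95% Jeffreys interval —
the 2.5% and 97.5% quantiles of $\mathrm{Beta}(k + \tfrac12,
n - k + \tfrac12)$, with the lower limit pinned to 0 at $k = 0$ and the
upper to 1 at $k = n$. Exact enumeration shows per-configuration coverage
stays above 90% (the $n{=}10, p{=}0.01$ corner sits at 90.4%) with
near-nominal average coverage. Distance profiles bin pairs into half-open
40 µm bins from zero (`distance_profile()`); distances are 3D Euclidean
intersomatic distances, and "within 100 µm" summaries are inclusive.
Group comparisons use the exact two-sided Fisher test on (connected,
unconnected) tables by the conventional probability-mass method, checked
in the tests against full hypergeometric enumeration. Percentages print to
one decimal.

## Problem sizes and numerical choices

The stochastic suites run at sizes chosen to make their statistical
assertions stable on a single CPU in minutes: the classifier benchmark uses
120 connected pairs (means log-spaced 0.05–2 mV, noise log-normal around
0.6 mV deconvolved RMS) against 360 background pairs at 20 kHz; detection
profiles use 8 injection repeats on 14-point grids; the corrected-
distribution round trip uses 400 true synapses against 6 per-pair detection
curves; STP recovery uses 100 noisy replicates. Amplitude-model moments are
checked at $10^5$–$10^6$ draws against the analytic product-moment CV.

Degenerate inputs are handled explicitly: flat traces fit to near-zero
amplitude with near-zero error; a flat all-ones STP curve drives parameters
to the bounds and is flagged; zero-mean amplitude lists make the CV an
error, not a number; empty histograms and single-class training sets raise
immediately. Ties in optimizer multi-starts resolve by best weighted error.

## Known limitations

The generator's noise is stationary and Gaussian; real recordings contain
spontaneous EPSPs, line noise, and slow drift that would degrade both the
detection limits and the KS features. The classifier is trained and
evaluated on the same synthetic family it is asked to detect, so its
accuracy here is an upper bound on real-data performance. The STP model
deliberately contains only depression and use-dependent replenishment;
facilitation-dominated synapses fit poorly by construction and should be
flagged by the bound/SE diagnostics rather than interpreted.
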