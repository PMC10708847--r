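---
title: "From raw vendor units to a beta-band attention index: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From raw vendor units to a beta-band attention index: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(betatrace)
```

## The measurement problem

betatrace analyses recordings from a low-cost, single-channel (Fp1, dry
electrode) EEG headset worn by several students at once during a classroom
task. The headset streams raw 512 Hz integer samples over a client–server
transport; the analysis question is whether the power of the beta band
(12–30 Hz) — a well-known electrophysiological correlate of alertness and
focused attention — carries information about each student's performance on
a graded task, and whether it can predict pass/fail outcomes.

The recording conditions are deliberately hostile: dry electrode, prefrontal
site (maximally exposed to eye blinks), mains hum, and free movement in a
real classroom. The pipeline therefore leans on a small number of robust,
conservative devices rather than on aggressive artifact correction.

## Signal chain

Raw vendor units convert to volts as
`volts = raw * (1.8 / 4096) / 2000` (ADC input range 1.8 V, 4096 steps,
amplifier gain 2000); one unit is about 0.22 µV. Samples are processed in
non-overlapping two-second epochs (1024 samples), assembled from the packet
stream; a sequence gap discards the window in progress rather than
zero-filling it, because silent zero-fill would bias the PSD downward.

Each epoch then passes through:

1. **Amplitude gate.** If any converted sample exceeds 75 µV in magnitude
   (strictly), the epoch is rejected. Scalp beta sits below ~30 µV while
   blinks at Fp1 reach well above 100 µV, so the gate removes blink and
   motion epochs wholesale. The gate runs *before* filtering: a bandpass
   smears a transient and can pull it below the threshold. Converted
   samples outside the ±100 µV physical validation range are clipped and
   counted first; such epochs are already doomed by the 75 µV gate.
2. **Butterworth bandpass 3–40 Hz, order 4, zero-phase.** The passband
   excludes mains hum (50 Hz) and screen flicker as well as sub-3 Hz drift.
   The filter is applied forward–backward, which squares the magnitude
   response and cancels phase distortion; this is an offline choice and is
   not what a causal real-time implementation would do. The order-4
   zero-phase response passes 50 Hz at a fraction 0.108 of 20 Hz in
   amplitude (0.012 in power), which the test suite asserts against an
   independently computed frequency response.
3. **Linear detrend and z-score.** Every surviving epoch ends with mean 0
   and standard deviation 1. Z-scoring equalizes epoch energy, so a few
   high-energy noisy epochs cannot dominate a session summary; the beta
   statistic becomes the *share* of epoch variance in 12–30 Hz.
4. **Welch PSD.** Tukey(0.15)-tapered segments of 256 samples (0.5 s,
   2 Hz bins) at 50% overlap, averaged, one-sided, scaled so the PSD
   integrates to the signal variance. The beta statistic sums
   `power × bin width` over bins with centers in the closed interval
   [12, 30] Hz — ten bins at this resolution.

A subject's session summary is the **mean** per-epoch beta power over
accepted epochs lying fully inside video-labeled segments of the session
annotation (surveys, quizzes, briefing and closing are excluded). The raw
source text for this statistic reads like a sum, but rejection leaves
unequal epoch counts across subjects, and a sum would confound attention
with blink rate; the mean is the default and a `summary_stat = "sum"`
switch preserves the alternative reading. Summaries are min–max normalized
to [0, 1] across the valid subjects of the whole cohort (not per sitting),
an order-preserving map that fixes the scale but none of the statistics
that follow.

### Numerical choices

- Zero-phase filtering uses odd-reflection end padding (a quarter epoch,
  256 samples). Without padding, a DC offset or trend produces edge
  transients from the slowly settling 3 Hz high-pass that leak into the
  epoch interior.
- A constant (zero-variance) epoch is flagged *degenerate* and discarded
  rather than divided by zero during z-scoring; degenerate counts are
  reported separately from artifact counts.
- Epochs are timed on the unbroken sample clock from session start; an
  epoch `[t, t + 2 s)` belongs to a video segment iff both endpoints lie
  within it.

## Statistical analyses

**Correlation.** The beta summary is correlated with the task score and
with each of six self-reported mental-state answers under three models:
Pearson, Spearman, and *skipped*. The skipped model guards the correlation
against bivariate outliers detected "relative to the overall structure":
the robust center is the minimum-covariance-determinant location; each data
point defines a projection direction through the center; all points are
projected on every such direction and flagged by the boxplot rule (1.5 IQR
beyond the ideal-fourths quartiles) on any of them. Flagged points are
removed and Spearman (by default; Pearson behind a flag) is computed on the
remainder. Confidence intervals are 95% percentile bootstrap with 2000
seeded resamples; for the skipped model the outlier set is detected once
and held fixed across resamples, since re-running the MCD inside every
resample is prohibitively expensive and would make the interval describe
the detector as much as the correlation. The reported *power* is the
post-hoc power of the correlation test under the Fisher-z approximation at
the observed r and n — a reporting convention, not a design quantity.

**Group analysis.** Best and worst performers are formed by excluding
subjects within ±0.5 of the mean score, splitting the rest at the pass mark
(worst strictly below), and trimming each group's beta values outside its
own [5th, 95th] percentile interval (linear-interpolation quantiles; for
groups up to 20 this removes exactly each group's minimum and maximum).
Shapiro–Wilk per group and Bartlett across groups screen the parametric
requirements; when any fails, the two-sided Mann–Whitney U test compares
the groups (midranks and normal approximation with tie correction, exact
enumeration for small tie-free groups), otherwise a pooled-variance t test.
Significance is declared at 5%.

**Classification.** Each subject contributes five features — mean beta per
video segment (4) plus the session mean (1), standardized across the
cohort — and a pass/fail label at the score threshold 5. A single-hidden-
layer multilayer perceptron (entropy loss, BFGS optimization, L2 weight
decay) is evaluated by leave-one-out cross-validation; inside each of the n
folds a 5-fold grid search over hidden width {2, 4, 8} and decay
{1e-4, 1e-3, 1e-2} selects hyperparameters on the training subjects only
(nested selection, so the held-out subject never leaks into its own model).
Pooled predictions yield the confusion matrix ("pass" positive, 0.5
threshold), recall/precision/accuracy/F1, the ROC over all distinct
probability cut-points, and the trapezoidal AUC.

Reported metrics are *truncated* (not rounded) to two decimals, the
convention that reproduces the platform's published digits (e.g. a recall
of 14/19 = 0.7368 reports as 0.73); full-precision values are always kept
alongside. One published metric, precision, is internally inconsistent in
its source (0.86 printed against 14/16 = 0.875 computed); betatrace reports
the formula value.

## The synthetic cohort: what it emulates and what it does not

No recordings ship with the package, so every stage is exercised against a
generator with known ground truth:

- per-subject traces are a sum of a 1/f (pink) background, Gaussian
  band-limited components in delta/theta/alpha/beta, a 50 Hz line
  sinusoid, and scheduled blink artifacts (smooth biphasic
  Gaussian-derivative bumps peaking well above the 75 µV gate), quantized
  to signed vendor units in [−2048, 2047];
- subject beta gains are log-normal (median 4 µV RMS, log-sd 0.5) against
  a background of delta 6 / theta 4 / alpha 5 / pink 8 µV RMS and a 2 µV
  line component — amplitudes in the range reported for scalp EEG, with
  beta below ~30 µV;
- task scores are built from the Gaussian latent behind the beta gain
  through a normal copula, calibrated so the *rank* association between
  true gain and score equals a requested target; scores live on a 0–10
  scale with mean 5 and SD 2.3 (the scale of the study cohort's score
  distribution), in quarter-point steps; blinks arrive at ~5/min;
- the six mental-state answers are drawn independently of beta gain, with
  the means and spreads of the study's answer table — by construction the
  null result, so correlation false-positive rates can be measured;
- the simulated session compresses the study's 28-minute protocol
  (briefing, 4 video segments with interleaved surveys and quizzes,
  closing) to 54 s with 8 s video segments: 16 analysis epochs per
  subject, enough for the session mean to stabilize while keeping the
  200-subject, 70-replicate recovery suite computable on one CPU. The
  generator accepts the real durations unchanged.

The generator is *not* physiological EEG: no non-stationarity, no alpha
blocking, no electrode drift, no correlated artifacts across subjects.
Passing the recovery suites therefore demonstrates that the chain is
implemented correctly and robust to the modeled noise — not that the
platform's empirical findings replicate on real classrooms, which requires
the original (request-only) recordings.

Under these conditions the package's recovery suite checks that, at
n = 200 and a planted rank association of 0.6, the skipped estimate falls
inside its own bootstrap CI in at least 90% of 50 seeded replicates and
detects the association essentially always, while 20 null cohorts keep
|r| ≤ 0.2 and hold correlation and group-test false positives near the
nominal 5% (binomial slack for 20 draws). A planted association of 0.9 at
n = 60 yields pooled LOOCV AUC above 0.8 end to end.

## Known limitations

- The per-packet sample count of the real transport is unspecified
  upstream; it is configurable (default 512 = 1 s) and the assembler is
  invariant to it on gap-free streams.
- Post-hoc power via Fisher z is an approximation and, at the observed r,
  is a deterministic function of r and n — it is reported because the
  platform's report format includes it.
- The skipped CI conditions on the detected outlier set (see above).
- The Mann–Whitney exact p-value is only used for small tie-free groups;
  elsewhere the tie-corrected normal approximation applies.
- Min–max normalization spans the whole cohort; if sessions were recorded
  in sittings with different hardware scaling, per-sitting normalization
  (not implemented as a default) could be preferable.
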