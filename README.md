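# betatrace

Offline analysis of low-cost, single-channel EEG attention monitoring for
the classroom. A dry-electrode headset on each student streams raw 512 Hz
integer samples to an acquisition server; **betatrace** turns those streams
into a per-subject *beta-band attention index* and asks whether it relates
to academic performance:

- **Signal chain** (per two-second, 1024-sample epoch): vendor-unit
  conversion `volts = raw × (1.8/4096)/2000`, a strict 75 µV
  amplitude gate that rejects blink/motion epochs, zero-phase Butterworth
  3–40 Hz, linear detrend, z-score, and a Welch PSD (Tukey 0.15 taper,
  256-sample segments, 50% overlap). The epoch statistic is the integrated
  power over the closed beta band **12–30 Hz**; the subject statistic is
  its mean over accepted epochs inside video-labeled session segments,
  min–max normalized to [0, 1] across the cohort.
- **Statistics**: Pearson, Spearman and *skipped* correlation (bivariate
  outliers flagged by projection from a minimum-covariance-determinant
  center, then rank correlation on the rest) with percentile-bootstrap
  CI95 and Fisher-z post-hoc power; best/worst performer groups (mean ±0.5
  score band excluded, split at the pass mark, per-group 5–95% beta trim)
  compared by Mann–Whitney U after Shapiro–Wilk/Bartlett screening.
- **Classification**: pass/fail from five standardized beta features
  (four video-segment means + session mean) with a grid-searched
  single-hidden-layer MLP under leave-one-out cross-validation; confusion
  metrics, ROC and trapezoidal AUC.
- **Synthetic cohorts**: a generator with known ground truth (1/f
  background, band-limited components, 50 Hz line, >75 µV blink bumps,
  vendor-unit quantization, and a tunable rank association between true
  beta gain and task score) makes every stage testable without any
  recordings.

All user-facing functions take and return tibbles and compose with the
pipe; fitted objects have `tidy()`/`glance()` methods and
`autoplot()`/`plot_*()` graphics.

## Worked example

Simulate a 24-student cohort whose true beta gain has rank association 0.6
with the task score, run the full chain, and analyse:

```r
library(betatrace)
library(dplyr)

coh <- generate_cohort(cohort_spec(n_subjects = 24, target_assoc = 0.6, seed = 42))
res <- lapply(names(coh$traces), function(id)
  process_subject(coh$traces[[id]], id, coh$annotation))
summaries <- normalize_cohort(bind_rows(lapply(res, \(r) r$summary)))
head(summaries[, c("subject_id", "n_kept", "n_rejected_artifact",
                   "total_mean_beta", "normalized_beta")], 4)
#> # A tibble: 4 × 5
#>   subject_id n_kept n_rejected_artifact total_mean_beta normalized_beta
#>   <chr>       <int>               <int>           <dbl>           <dbl>
#> 1 S001           14                   2           0.580           0.708
#> 2 S002           12                   4           0.324           0.188
#> 3 S003           11                   5           0.454           0.451
#> 4 S004           13                   3           0.431           0.404
```

Each subject watched four 8 s video segments (16 two-second epochs in the
analysis mask); blink artifacts cost a few epochs (`n_rejected_artifact`),
and `total_mean_beta` is the mean beta share of epoch variance —
`normalized_beta` rescales it to [0, 1] across the cohort.

```r
merged <- inner_join(summaries, coh$subjects, by = "subject_id")
correlate(merged, x = "normalized_beta", y = "score", model = "skipped", seed = 1)
#> <beta_cor> skipped (spearman): r = 0.783, CI95 [0.555, 0.904], p = 6.21e-06, power = 1.00
```

The skipped correlation recovers the planted positive association (the
estimate exceeds the planted 0.6 by sampling noise at n = 24; no outliers
were flagged, so it coincides with Spearman here). The group contrast and
the classifier tell the same story:

```r
compare_groups(form_groups(merged, scores = "score", betas = "total_mean_beta"))
#> <beta_group_test> t_test: statistic = -8.590, p = 3.548e-07 (significant at alpha = 0.05)
#>   worst: n = 10, median = 0.3366 | best: n = 7, median = 0.5687

feats <- make_features(bind_rows(lapply(res, \(r) r$epochs)), summaries,
                       coh$annotation, coh$subjects)
evaluate_predictions(loocv_predict(feats, seed = 1))
#> <beta_clf_report> n = 24
#>   confusion: TP=10 FP=4 FN=2 TN=8 (threshold 0.50)
#>   recall 0.83 | precision 0.71 | accuracy 0.75 | F1 0.76 | AUC 0.86
```

(Here the groups happened to pass the normality/variance screen, so the t
test was used; on skewed beta distributions the Mann–Whitney U takes over.)
The whole sequence — simulation, epoch processing, statistics,
classification, with every product written to disk — is also available as
`run_pipeline(run_config(...))` and through the thin command-line wrapper
`inst/cli/betatrace.R`.

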