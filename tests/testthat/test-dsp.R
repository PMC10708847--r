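cfg <- processing_config()

test_that("the 75 uV artifact gate is strict and length-checked", {
  base <- rep(0, 1024)
  spike <- base; spike[500] <- 80
  expect_true(is_artifact(spike))
  expect_false(is_artifact(base + 74.9 * sin(2 * pi * 10 * (0:1023) / 512)))
  at_gate <- base; at_gate[10] <- 75
  expect_false(is_artifact(at_gate)) # exactly at threshold: accepted
  expect_true(is_artifact(base - 76)) # magnitude, not signed value
  expect_error(is_artifact(rep(0, 1000), epoch_len = 1024), "1000")
})

test_that("preprocessing yields a zero-mean unit-variance epoch", {
  withr::with_seed(4, {
    for (i in 1:5) {
      x <- preprocess_epoch(rnorm(1024, sd = 10) +
                              sine_epoch(17, amp = 8), cfg)
      expect_lt(abs(mean(x)), 1e-9)
      expect_lt(abs(sd(x) - 1), 1e-9)
      expect_false(attr(x, "degenerate"))
    }
  })
})

test_that("DC offsets and trends are removed before z-scoring", {
  pure <- sine_epoch(20)
  shifted <- pure + 50 + 10 * seq(0, 1, length.out = 1024)
  a <- preprocess_epoch(pure, cfg)
  b <- preprocess_epoch(shifted, cfg)
  expect_gt(cor(a, b), 0.99)
})

test_that("a constant epoch is flagged degenerate, not divided by zero", {
  x <- preprocess_epoch(rep(42, 1024), cfg)
  expect_true(attr(x, "degenerate"))
  expect_true(all(x == 0))
})

test_that("the 3-40 Hz Butterworth crushes 50 Hz relative to 20 Hz", {
  # independent frequency-response oracle for the chosen order: filter pure
  # tones with the same design directly through the signal package
  filt <- signal::butter(4, c(3, 40) / 256, type = "pass")
  rms <- function(f) {
    y <- signal::filtfilt(filt, sine_epoch(f, amp = 1, n = 4096))
    sqrt(mean(y[1025:3072]^2)) # interior, away from edge transients
  }
  # the order-4 zero-phase response ratio |H(50)/H(20)|^2 is 0.108
  expect_lte(rms(50) / rms(20), 0.11)

  # and the full chain shows the squared suppression in the PSD domain
  mix <- sine_epoch(20, amp = 10) + sine_epoch(50, amp = 10)
  p <- welch_psd(preprocess_epoch(mix, cfg), cfg)
  expect_lte(p$power[p$freq == 50] / p$power[p$freq == 20], 0.013)
})

test_that("welch spectrum of white noise is flat across the passband", {
  withr::with_seed(11, {
    ratios <- replicate(10, {
      p <- welch_psd(preprocess_epoch(rnorm(1024, sd = 5), cfg), cfg)
      beta <- mean(p$power[p$freq >= 12 & p$freq <= 30])
      low <- mean(p$power[p$freq >= 3 & p$freq < 12])
      beta / low
    })
    expect_true(all(ratios < 3 & ratios > 1 / 3))
  })
})

test_that("welch peak lands on an injected tone and Parseval holds", {
  x <- preprocess_epoch(sine_epoch(20) + rnorm(1024, sd = 0.5), cfg)
  p <- welch_psd(x, cfg)
  expect_equal(p$freq[which.max(p$power)], 20)
  expect_equal(diff(p$freq[1:2]), 2) # fs / segment = 512/256
  total <- sum(p$power) * attr(p, "df")
  expect_lt(abs(total - 1), 0.25) # z-scored epoch has unit variance
})

test_that("a one-segment welch equals the direct tapered periodogram", {
  cfg1 <- processing_config(welch_segment_len = 1024)
  withr::with_seed(12, x <- rnorm(1024))
  x <- preprocess_epoch(x, cfg1)
  p <- welch_psd(x, cfg1)
  oracle <- direct_periodogram(as.numeric(x), 512, 0.15)
  expect_equal(p$freq, oracle$freq)
  expect_equal(p$power, oracle$power, tolerance = 1e-12)
})

test_that("welch rejects a segment longer than the epoch", {
  expect_error(welch_psd(rnorm(128), processing_config()), "segment")
  expect_error(processing_config(welch_segment_len = 4096), "exceed")
})

test_that("band power integrates bins and is additive over a partition", {
  p <- welch_psd(preprocess_epoch(sine_epoch(20) + rnorm(1024, sd = 0.1),
                                  cfg), cfg)
  zero <- p; zero$power <- rep(0, nrow(p))
  expect_equal(band_power(zero), 0)

  single <- zero; single$power[single$freq == 20] <- 3
  expect_equal(band_power(single, c(12, 30)), band_power(single, c(0, 256)))

  total <- band_power(p, c(3, 40))
  parts <- band_power(p, c(3, 12)) +
    band_power(p, c(12, 30), left_closed = FALSE) +
    band_power(p, c(30, 40), left_closed = FALSE)
  expect_equal(parts, total, tolerance = 1e-12)

  expect_error(band_power(p, c(300, 400)), "band")
})

test_that("subject summaries mask non-video epochs and count every epoch", {
  ann <- session_annotation(data.frame(
    label = c("briefing", "video", "survey", "video"),
    start_s = c(0, 4, 12, 16), end_s = c(4, 12, 16, 24)
  ))
  processed <- tibble::tibble(
    subject_id = "S001",
    epoch_index = 0:11,
    start_s = seq(0, 22, by = 2),
    status = c("ok", "ok", "ok", "artifact", "ok", "ok",
               "ok", "ok", "degenerate", "ok", "ok", "ok"),
    n_clipped = 0L,
    beta_power = rep(2.5, 12)
  )
  s <- summarize_subject(processed, ann, cfg)
  # video epochs: starts 4,6,8,10 and 16,18,20,22 -> 8 in-mask
  expect_equal(s$n_excluded_by_mask, 4)
  expect_equal(s$n_rejected_artifact, 1) # the in-mask epoch starting at 6 s
  expect_equal(s$n_rejected_degenerate, 1)
  expect_equal(s$n_excluded_by_mask + s$n_rejected_artifact +
                 s$n_rejected_degenerate + s$n_kept, s$n_epochs_total)
  expect_equal(s$total_mean_beta, 2.5) # every kept epoch has power 2.5
  expect_true(s$valid)
})

test_that("a subject with only artifact epochs is flagged invalid", {
  processed <- tibble::tibble(
    subject_id = "S002", epoch_index = 0:3, start_s = seq(0, 6, 2),
    status = "artifact", n_clipped = 0L, beta_power = NA_real_
  )
  expect_warning(s <- summarize_subject(processed, video_annotation(8), cfg),
                 "invalid")
  expect_false(s$valid)
  expect_true(is.na(s$total_mean_beta))
})

test_that("cohort normalization is a min-max map preserving order", {
  summ <- tibble::tibble(
    subject_id = c("a", "b", "c"),
    total_mean_beta = c(2, 4, 6),
    valid = TRUE
  )
  out <- normalize_cohort(summ)
  expect_equal(out$normalized_beta, c(0, 0.5, 1))
  withr::with_seed(3, {
    x <- runif(20, 1, 9)
    out2 <- normalize_cohort(tibble::tibble(
      subject_id = as.character(1:20), total_mean_beta = x, valid = TRUE
    ))
    expect_equal(rank(out2$normalized_beta), rank(x))
    expect_equal(min(out2$normalized_beta), 0)
    expect_equal(max(out2$normalized_beta), 1)
  })
  summ$total_mean_beta <- c(3, 3, 3)
  expect_error(normalize_cohort(summ), "identical")
})

test_that("session annotations are validated and survive JSON round trip", {
  expect_error(session_annotation(data.frame(
    label = "video", start_s = 4, end_s = 2
  )), "start_s < end_s")
  expect_error(session_annotation(data.frame(
    label = c("video", "survey"), start_s = c(0, 3), end_s = c(4, 6)
  )), "non-overlapping")
  expect_error(session_annotation(data.frame(
    label = "lecture", start_s = 0, end_s = 4
  )), "labels")
  dir <- withr::local_tempdir()
  ann <- video_annotation(16)
  p <- file.path(dir, "ann.json")
  write_annotation_json(ann, p)
  expect_equal(as.data.frame(read_annotation_json(p)), as.data.frame(ann))
})

test_that("total mean beta increases with the generated beta gain", {
  ann <- video_annotation(20)
  betas <- vapply(c(2, 4, 8), function(g) {
    tr <- generate_trace(signal_spec(
      20, band_gains = c(delta = 6, theta = 4, alpha = 5, beta = g),
      pink_gain = 8, seed = 31
    ))
    process_subject(tr, "S001", ann, cfg)$summary$total_mean_beta
  }, numeric(1))
  expect_true(all(diff(betas) > 0))
})

test_that("one blink removes exactly the epochs it touches", {
  quiet <- signal_spec(20, band_gains = c(beta = 3), pink_gain = 2, seed = 44)
  ann <- video_annotation(20)
  clean <- process_subject(generate_trace(quiet), "S001", ann, cfg)$summary
  expect_equal(clean$n_rejected_artifact, 0)

  # blink centered at 3.0 s, width 0.3 s: its super-threshold excursion
  # lives in (2.7, 3.3) at the widest, inside the single epoch [2, 4)
  blink <- signal_spec(20, band_gains = c(beta = 3), pink_gain = 2,
                       blink_schedule = data.frame(
                         onset_s = 3.0, peak_uV = 150, width_s = 0.3
                       ), seed = 44)
  dirty <- process_subject(generate_trace(blink), "S001", ann, cfg)$summary
  expect_equal(dirty$n_rejected_artifact, 1)
  expect_equal(clean$n_kept - dirty$n_kept, 1)
})

test_that("processing config invariants are enforced", {
  expect_error(processing_config(fs = 512, epoch_len = 512), "2 \\* fs")
  expect_error(processing_config(beta_band = c(12, 45)), "bandpass")
  expect_error(processing_config(welch_overlap = 1), "overlap")
})
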