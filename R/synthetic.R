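#' Specification of a synthetic single-channel EEG trace
#'
#' Describes one subject's raw recording: a 1/f (pink) background, Gaussian
#' band-limited components in the four canonical bands, an optional power-line
#' sinusoid, optional pure tones (for spectral tests), and scheduled blink
#' artifacts. Amplitudes are microvolt RMS values except for blinks and tones,
#' which are peak amplitudes.
#'
#' @param duration_s Trace duration in seconds (> 0).
#' @param fs Sampling rate in Hz (default 512).
#' @param band_gains Named numeric vector of uV RMS gains for the
#'   `delta` (1-4 Hz), `theta` (4-8 Hz), `alpha` (8-12 Hz) and `beta`
#'   (12-30 Hz) components. Missing names default to 0.
#' @param pink_gain uV RMS of the 1/f background.
#' @param line_amp_uV Peak amplitude in uV of the `line_freq_hz` sinusoid.
#' @param line_freq_hz Power-line frequency in Hz (default 50).
#' @param tones Optional data frame with columns `freq_hz`, `amp_uV`: pure
#'   sinusoids added deterministically (no randomness), mainly for oracle
#'   tests of the spectral chain.
#' @param blink_schedule Optional data frame with columns `onset_s` (blink
#'   center time), `peak_uV` (peak magnitude) and `width_s` (approximate
#'   total duration). Blinks are smooth biphasic Gaussian-derivative bumps.
#' @param seed Integer seed; a fixed seed gives a bit-identical trace.
#'
#' @return A list of class `signal_spec`.
#' @seealso [generate_trace()]
#' @export
signal_spec <- function(duration_s, fs = 512,
                        band_gains = c(delta = 0, theta = 0, alpha = 0, beta = 0),
                        pink_gain = 0, line_amp_uV = 0, line_freq_hz = 50,
                        tones = NULL, blink_schedule = NULL, seed = 1L) {
  if (!is.numeric(duration_s) || duration_s <= 0) {
    abort("`duration_s` must be a positive number.")
  }
  if (!is.numeric(fs) || fs <= 0) abort("`fs` must be a positive number.")
  gains <- c(delta = 0, theta = 0, alpha = 0, beta = 0)
  if (length(band_gains)) {
    bad <- setdiff(names(band_gains), names(gains))
    if (length(bad)) abort(paste0("Unknown band name(s): ", toString(bad)))
    gains[names(band_gains)] <- band_gains
  }
  if (any(gains < 0) || pink_gain < 0 || line_amp_uV < 0) {
    abort("All gains and amplitudes must be non-negative.")
  }
  if (!is.null(blink_schedule)) {
    blink_schedule <- as_tibble(blink_schedule)
    stopifnot(all(c("onset_s", "peak_uV", "width_s") %in% names(blink_schedule)))
    if (nrow(blink_schedule) &&
        any(blink_schedule$onset_s < 0 | blink_schedule$onset_s >= duration_s)) {
      abort("Blink onsets must lie within [0, duration_s).")
    }
  }
  if (!is.null(tones)) {
    tones <- as_tibble(tones)
    stopifnot(all(c("freq_hz", "amp_uV") %in% names(tones)))
  }
  structure(
    list(duration_s = duration_s, fs = fs, band_gains = gains,
         pink_gain = pink_gain, line_amp_uV = line_amp_uV,
         line_freq_hz = line_freq_hz, tones = tones,
         blink_schedule = blink_schedule, seed = as.integer(seed)),
    class = "signal_spec"
  )
}

# Frequency edges (Hz) of the canonical generation bands.
band_edges <- function() {
  list(delta = c(1, 4), theta = c(4, 8), alpha = c(8, 12), beta = c(12, 30))
}

# Gaussian noise confined to [lo, hi] Hz by zeroing FFT bins, scaled to a
# target RMS. Returns the zero vector when gain is 0.
band_noise <- function(n, fs, lo, hi, rms) {
  if (rms <= 0) return(numeric(n))
  x <- rnorm(n)
  f <- fft_freqs(n, fs)
  keep <- abs(f) >= lo & abs(f) <= hi
  xf <- fft(x)
  xf[!keep] <- 0
  y <- Re(fft(xf, inverse = TRUE)) / n
  y * rms / sqrt(mean(y^2))
}

# 1/f-amplitude background: white noise shaped in the frequency domain,
# flat below 1 Hz, DC removed, scaled to a target RMS.
pink_noise <- function(n, fs, rms) {
  if (rms <= 0) return(numeric(n))
  x <- rnorm(n)
  f <- abs(fft_freqs(n, fs))
  shape <- 1 / sqrt(pmax(f, 1))
  shape[1] <- 0
  xf <- fft(x) * shape
  y <- Re(fft(xf, inverse = TRUE)) / n
  y * rms / sqrt(mean(y^2))
}

# Signed FFT bin frequencies for an n-point transform at rate fs.
fft_freqs <- function(n, fs) {
  k <- c(seq(0, floor(n / 2)), seq(-ceiling(n / 2) + 1, -1))
  k * fs / n
}

# Biphasic blink bump: normalized Gaussian derivative centered at onset_s,
# peak magnitude peak_uV, effective width width_s (~4 sigma).
blink_pulse <- function(t, onset_s, peak_uV, width_s) {
  sigma <- width_s / 4
  u <- (t - onset_s) / sigma
  peak_uV * (-u) * exp((1 - u^2) / 2)
}

#' Generate a raw vendor-unit EEG trace
#'
#' Sums the components described by a [signal_spec()] in microvolts, then
#' quantizes to signed vendor units through the inverse of the headset's
#' volts-per-unit conversion (see [uv_to_raw()]). The pre-quantization
#' microvolt signal is kept alongside the integer stream so tests can check
#' the quantization round trip.
#'
#' @param spec A [signal_spec()].
#'
#' @return A tibble with columns `sample_index` (0-based integer), `raw_value`
#'   (signed vendor units) and `uv` (pre-quantization microvolts), with
#'   attributes `fs` and `seed`. Exactly `round(duration_s * fs)` rows.
#'
#' @details If quantization would clip more than 1% of samples the function
#'   aborts, naming the largest component, since such a trace would be
#'   dominated by saturation rather than signal.
#' @examples
#' tr <- generate_trace(signal_spec(2, band_gains = c(beta = 5), seed = 42))
#' nrow(tr) # 1024
#' @export
generate_trace <- function(spec) {
  stopifnot(inherits(spec, "signal_spec"))
  n <- round(spec$duration_s * spec$fs)
  t <- seq_len(n) / spec$fs - 1 / spec$fs
  edges <- band_edges()
  parts <- withr::with_seed(spec$seed, {
    p <- list(pink = pink_noise(n, spec$fs, spec$pink_gain))
    for (b in names(edges)) {
      p[[b]] <- band_noise(n, spec$fs, edges[[b]][1], edges[[b]][2],
                           spec$band_gains[[b]])
    }
    p
  })
  parts$line <- if (spec$line_amp_uV > 0) {
    spec$line_amp_uV * sin(2 * pi * spec$line_freq_hz * t)
  } else numeric(n)
  parts$tones <- numeric(n)
  if (!is.null(spec$tones) && nrow(spec$tones)) {
    for (i in seq_len(nrow(spec$tones))) {
      parts$tones <- parts$tones +
        spec$tones$amp_uV[i] * sin(2 * pi * spec$tones$freq_hz[i] * t)
    }
  }
  parts$blinks <- numeric(n)
  if (!is.null(spec$blink_schedule) && nrow(spec$blink_schedule)) {
    for (i in seq_len(nrow(spec$blink_schedule))) {
      parts$blinks <- parts$blinks +
        blink_pulse(t, spec$blink_schedule$onset_s[i],
                    spec$blink_schedule$peak_uV[i],
                    spec$blink_schedule$width_s[i])
    }
  }
  uv <- Reduce(`+`, parts)
  raw <- uv_to_raw(uv)
  if (attr(raw, "n_clipped") > 0.01 * n) {
    peaks <- vapply(parts, function(p) max(abs(p)), numeric(1))
    abort(paste0(
      "Component '", names(which.max(peaks)), "' drives more than 1% of ",
      "samples into ADC clipping; lower its gain."
    ))
  }
  out <- tibble(
    sample_index = seq_len(n) - 1L,
    raw_value = as.integer(raw),
    uv = uv
  )
  attr(out, "fs") <- spec$fs
  attr(out, "seed") <- spec$seed
  out
}

#' Specification of a synthetic study cohort
#'
#' Describes a cohort in which each subject's beta-band RMS gain is drawn from
#' a log-normal distribution and task scores share a configurable monotone
#' (rank) association with that gain, while the six mental-state answers are
#' generated independently of it — mirroring a study in which self-reports
#' carried no signal about measured beta power.
#'
#' @param n_subjects Number of subjects (>= 1 for non-empty output).
#' @param target_assoc Target Spearman association in `[-1, 1]` between the
#'   true beta gain and the task score.
#' @param score_noise_sd Additional score noise (score units) on top of the
#'   association-controlled construction; default 0.
#' @param pass_mark Pass threshold in score units (default 5).
#' @param seed Integer seed.
#' @param segment_s Duration in seconds of each of the four video segments
#'   of the simulated session (default 8).
#' @param blink_rate_hz Mean blink rate per second (default 1/12).
#'
#' @return A list of class `cohort_spec`.
#' @details Scores are built from a latent bivariate-normal construction:
#'   the Gaussian latent `z` behind the log-normal beta gain is mixed with
#'   independent noise at Pearson correlation `rho = 2 sin(pi * target / 6)`,
#'   the inverse of the normal-copula Spearman map, so the rank association
#'   between gain and score approaches `target_assoc` as n grows. The latent
#'   is mapped affinely to a 0-10 score scale (mean 5, sd 2.3, the scale of a
#'   typical classroom quiz), clamped and rounded to quarter points.
#' @export
cohort_spec <- function(n_subjects, target_assoc = 0.6, score_noise_sd = 0,
                        pass_mark = 5, seed = 1L, segment_s = 8,
                        blink_rate_hz = 1 / 12) {
  if (!is.numeric(n_subjects) || n_subjects < 0) {
    abort("`n_subjects` must be a non-negative count.")
  }
  if (abs(target_assoc) > 1) abort("`target_assoc` must lie in [-1, 1].")
  if (score_noise_sd < 0) abort("`score_noise_sd` must be non-negative.")
  structure(
    list(n_subjects = as.integer(n_subjects), target_assoc = target_assoc,
         score_noise_sd = score_noise_sd, pass_mark = pass_mark,
         seed = as.integer(seed), segment_s = segment_s,
         blink_rate_hz = blink_rate_hz),
    class = "cohort_spec"
  )
}

# Session timeline scaled from the real protocol: briefing, then four
# (video, survey, quiz) blocks, then closing. Segment boundaries fall on the
# 2-s epoch grid so each video segment contributes segment_s/2 epochs.
cohort_session <- function(segment_s = 8, survey_s = 2, quiz_s = 2,
                           briefing_s = 4, closing_s = 2) {
  segs <- list(tibble(label = "briefing", start_s = 0, end_s = briefing_s))
  t0 <- briefing_s
  for (i in 1:4) {
    segs <- c(segs, list(
      tibble(label = "video", start_s = t0, end_s = t0 + segment_s),
      tibble(label = "survey", start_s = t0 + segment_s,
             end_s = t0 + segment_s + survey_s),
      tibble(label = "quiz", start_s = t0 + segment_s + survey_s,
             end_s = t0 + segment_s + survey_s + quiz_s)
    ))
    t0 <- t0 + segment_s + survey_s + quiz_s
  }
  segs <- c(segs, list(tibble(label = "closing", start_s = t0,
                              end_s = t0 + closing_s)))
  session_annotation(dplyr::bind_rows(segs))
}

# Mental-state answer scales (Likert means): location/spread per question,
# independent of beta gain.
answer_scales <- function() {
  tibble(
    question = c("attention", "stress", "relaxation", "interest",
                 "fatigue", "effort"),
    mean = c(4.3, 1.7, 3.3, 4.3, 2.2, 2.7),
    sd = c(0.5, 0.6, 0.8, 0.5, 0.7, 0.9)
  )
}

#' Generate a synthetic cohort with known ground truth
#'
#' Draws per-subject beta gains, constructs task scores with the requested
#' rank association to those gains, samples six independent mental-state
#' answers, and synthesizes one raw trace per subject over a session timeline
#' with four video segments (see [cohort_spec()]).
#'
#' @param cspec A [cohort_spec()].
#'
#' @return A list of class `beta_cohort` with elements:
#'   * `subjects`: tibble with `subject_id`, `score`, the six answer columns,
#'     and the ground-truth `beta_gain`;
#'   * `traces`: named list of raw-trace tibbles (one per subject);
#'   * `annotation`: the session annotation tibble;
#'   * `spec`: the input spec.
#' @examples
#' coh <- generate_cohort(cohort_spec(3, seed = 7))
#' coh$subjects
#' @export
generate_cohort <- function(cspec) {
  stopifnot(inherits(cspec, "cohort_spec"))
  n <- cspec$n_subjects
  if (n == 0) abort("Cannot generate an empty cohort (`n_subjects` = 0).")
  annotation <- cohort_session(segment_s = cspec$segment_s)
  duration <- max(annotation$end_s)
  withr::with_seed(cspec$seed, {
    z <- rnorm(n)
    beta_gain <- exp(log(4) + 0.5 * z)
    rho <- 2 * sin(pi * cspec$target_assoc / 6)
    latent <- rho * z + sqrt(1 - rho^2) * rnorm(n)
    score <- 5 + 2.3 * latent + rnorm(n, 0, cspec$score_noise_sd)
    score <- round(pmin(pmax(score, 0), 10) * 4) / 4
    scales <- answer_scales()
    answers <- purrr::map(seq_len(nrow(scales)), function(i) {
      pmin(pmax(rnorm(n, scales$mean[i], scales$sd[i]), 1), 5)
    })
    names(answers) <- scales$question
    trace_seeds <- sample.int(.Machine$integer.max - 1L, n)
    subjects <- tibble(
      subject_id = sprintf("S%03d", seq_len(n)),
      score = score,
      !!!answers,
      beta_gain = beta_gain
    )
    traces <- purrr::map(seq_len(n), function(i) {
      n_blinks <- stats::rpois(1, cspec$blink_rate_hz * duration)
      blinks <- if (n_blinks > 0) {
        tibble(onset_s = runif(n_blinks, 0.5, duration - 0.5),
               peak_uV = runif(n_blinks, 110, 190),
               width_s = runif(n_blinks, 0.25, 0.4))
      } else NULL
      generate_trace(signal_spec(
        duration_s = duration,
        band_gains = c(delta = 6, theta = 4, alpha = 5, beta = beta_gain[i]),
        pink_gain = 8, line_amp_uV = 2,
        blink_schedule = blinks,
        seed = trace_seeds[i]
      ))
    })
    names(traces) <- subjects$subject_id
    structure(
      list(subjects = subjects, traces = traces, annotation = annotation,
           spec = cspec),
      class = "beta_cohort"
    )
  })
}

#' @export
print.beta_cohort <- function(x, ...) {
  cat("<beta_cohort> ", nrow(x$subjects), " subjects, session ",
      max(x$annotation$end_s), " s (",
      sum(x$annotation$label == "video"), " video segments)\n", sep = "")
  print(x$subjects, n = 5)
  invisible(x)
}

#' Write or read a raw trace as CSV with a JSON sidecar
#'
#' The CSV holds `sample_index,raw_value`; the sidecar echoes subject id,
#' sampling rate and generator seed so a directory of traces is
#' self-describing.
#'
#' @param trace A trace tibble from [generate_trace()] (or with at least
#'   `sample_index` and `raw_value` columns).
#' @param path CSV output path; the sidecar is written at `<path>.json`.
#' @param subject_id Subject identifier recorded in the sidecar.
#' @param fs Sampling rate recorded in the sidecar.
#' @return `write_trace_csv()` returns `path` invisibly; `read_trace_csv()`
#'   returns a trace tibble with `fs` and `subject_id` attributes.
#' @export
write_trace_csv <- function(trace, path, subject_id = "S001",
                            fs = attr(trace, "fs") %||% 512) {
  readr::write_csv(trace[, c("sample_index", "raw_value")], path)
  sidecar <- list(subject_id = subject_id, fs = fs,
                  seed = attr(trace, "seed"),
                  n_samples = nrow(trace))
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  out <- readr::read_csv(path, col_types = readr::cols(
    sample_index = readr::col_integer(),
    raw_value = readr::col_integer()
  ))
  sidecar_path <- paste0(path, ".json")
  if (file.exists(sidecar_path)) {
    meta <- jsonlite::read_json(sidecar_path)
    attr(out, "fs") <- meta$fs
    attr(out, "subject_id") <- meta$subject_id
  }
  out
}

#' Write a cohort's subject table to CSV
#'
#' Columns: `subject_id,score,attention,stress,relaxation,interest,fatigue,
#' effort`. The ground-truth `beta_gain` column, when present, is dropped on
#' write: downstream stages must estimate beta power from the traces.
#'
#' @param subjects Subject tibble (e.g. `generate_cohort(...)$subjects`).
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(subjects, path) {
  keep <- c("subject_id", "score", "attention", "stress", "relaxation",
            "interest", "fatigue", "effort")
  readr::write_csv(subjects[, intersect(keep, names(subjects))], path)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    subject_id = readr::col_character(),
    .default = readr::col_double()
  ))
}
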