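#' Processing configuration for the per-epoch beta-power chain
#'
#' Bundles every tunable of the signal chain: sampling rate, epoch length,
#' the artifact amplitude gate, the Butterworth passband, the Tukey taper
#' fraction, the Welch segmentation, the beta band and the physical
#' amplitude validation range.
#'
#' @param fs Sampling rate in Hz.
#' @param epoch_len Samples per epoch; must equal `2 * fs` (two-second
#'   windows).
#' @param artifact_threshold_uV Absolute-amplitude rejection gate in uV
#'   (default 75): an epoch with any sample strictly above it is rejected.
#' @param bandpass Butterworth passband in Hz (default 3-40), removing both
#'   mains hum at 50 Hz and sub-3 Hz drift/flicker.
#' @param butter_order Butterworth order (default 4), applied
#'   forward-backward for zero phase.
#' @param tukey_fraction Taper fraction of the Tukey window applied to each
#'   Welch segment (default 0.15).
#' @param welch_segment_len Welch segment length in samples (default 256,
#'   i.e. 0.5 s and a 2 Hz bin width, resolving the beta band into 10 bins).
#' @param welch_overlap Fractional overlap of Welch segments (default 0.5).
#' @param beta_band Beta band in Hz, closed interval (default 12-30).
#' @param amplitude_range_uV Physical validation range in uV; converted
#'   samples outside it are clipped and counted (default c(-100, 100)).
#' @param summary_stat Per-subject session summary over accepted in-mask
#'   epochs: `"mean"` (default) or `"sum"` of per-epoch beta power. The mean
#'   is the default because artifact rejection leaves unequal epoch counts
#'   across subjects, which a sum would confound with attention.
#'
#' @return A list of class `processing_config`.
#' @export
processing_config <- function(fs = 512, epoch_len = 2 * fs,
                              artifact_threshold_uV = 75,
                              bandpass = c(3, 40), butter_order = 4,
                              tukey_fraction = 0.15,
                              welch_segment_len = 256, welch_overlap = 0.5,
                              beta_band = c(12, 30),
                              amplitude_range_uV = c(-100, 100),
                              summary_stat = c("mean", "sum")) {
  summary_stat <- match.arg(summary_stat)
  if (epoch_len != 2 * fs) abort("`epoch_len` must equal 2 * fs.")
  if (!(beta_band[1] >= bandpass[1] && beta_band[2] <= bandpass[2])) {
    abort("`beta_band` must lie within `bandpass`.")
  }
  if (welch_overlap <= 0 || welch_overlap >= 1) {
    abort("`welch_overlap` must lie strictly between 0 and 1.")
  }
  if (welch_segment_len > epoch_len) {
    abort("`welch_segment_len` cannot exceed `epoch_len`.")
  }
  structure(
    list(fs = fs, epoch_len = as.integer(epoch_len),
         artifact_threshold_uV = artifact_threshold_uV,
         bandpass = bandpass, butter_order = butter_order,
         tukey_fraction = tukey_fraction,
         welch_segment_len = as.integer(welch_segment_len),
         welch_overlap = welch_overlap, beta_band = beta_band,
         amplitude_range_uV = amplitude_range_uV,
         summary_stat = summary_stat),
    class = "processing_config"
  )
}

#' Session annotation: labeled time segments
#'
#' A session is annotated with non-overlapping, ascending segments labeled
#' `video`, `survey`, `quiz`, `briefing` or `closing`. Only epochs fully
#' inside `video` segments enter the subject summary.
#'
#' @param segments Data frame with columns `label`, `start_s`, `end_s`.
#' @return A tibble of class `session_annotation`.
#' @export
session_annotation <- function(segments) {
  segments <- as_tibble(segments)
  stopifnot(all(c("label", "start_s", "end_s") %in% names(segments)))
  ok_labels <- c("video", "survey", "quiz", "briefing", "closing")
  if (!all(segments$label %in% ok_labels)) {
    abort(paste0("Segment labels must be one of: ", toString(ok_labels)))
  }
  if (any(segments$end_s <= segments$start_s)) {
    abort("Each segment must satisfy start_s < end_s.")
  }
  if (is.unsorted(segments$start_s, strictly = TRUE) ||
      any(utils::head(segments$end_s, -1) > utils::tail(segments$start_s, -1))) {
    abort("Segments must be ascending and non-overlapping.")
  }
  class(segments) <- c("session_annotation", class(segments))
  segments
}

#' @rdname session_annotation
#' @param annotation A `session_annotation`.
#' @param path JSON path.
#' @export
write_annotation_json <- function(annotation, path) {
  jsonlite::write_json(as.data.frame(annotation), path, digits = NA)
  invisible(path)
}

#' @rdname session_annotation
#' @export
read_annotation_json <- function(path) {
  session_annotation(jsonlite::fromJSON(path))
}

#' Amplitude-threshold artifact gate
#'
#' Flags an epoch for rejection when any sample's magnitude strictly exceeds
#' the threshold. Blinks and motion transients at the prefrontal electrode
#' reach well beyond 75 uV while scalp beta stays below ~30 uV, so the gate
#' runs on converted microvolts *before* filtering (filtering smears and
#' shrinks transients below the gate).
#'
#' @param epoch_uv Numeric vector, one epoch in microvolts.
#' @param threshold_uV Gate in uV (default 75). A peak of exactly 75 uV is
#'   accepted (strict inequality).
#' @param epoch_len Expected epoch length; a mismatch is an error.
#' @return `TRUE` if the epoch must be rejected.
#' @examples
#' is_artifact(rep(0, 1024))
#' @export
is_artifact <- function(epoch_uv, threshold_uV = 75,
                        epoch_len = length(epoch_uv)) {
  if (length(epoch_uv) != epoch_len) {
    abort(paste0("Epoch has ", length(epoch_uv), " samples; expected ",
                 epoch_len, "."))
  }
  max(abs(epoch_uv)) > threshold_uV
}

# Tukey (tapered cosine) window of length n with taper fraction r.
tukey_window <- function(n, r = 0.15) {
  if (r <= 0) return(rep(1, n))
  if (r >= 1) return(0.5 * (1 - cos(2 * pi * seq(0, 1, length.out = n))))
  x <- seq(0, 1, length.out = n)
  w <- rep(1, n)
  left <- x < r / 2
  right <- x >= 1 - r / 2
  w[left] <- 0.5 * (1 + cos(2 * pi / r * (x[left] - r / 2)))
  w[right] <- 0.5 * (1 + cos(2 * pi / r * (x[right] - 1 + r / 2)))
  w
}

# Remove the least-squares straight line from x.
detrend_linear <- function(x) {
  n <- length(x)
  t <- seq_len(n) - (n + 1) / 2           # centered time axis
  x - mean(x) - t * (sum(t * x) / sum(t * t))
}

# Cache the zero-phase Butterworth for a config (filter design is costly
# relative to applying it to a 1024-sample epoch).
butter_for <- function(cfg) {
  key <- paste(cfg$butter_order, cfg$bandpass[1], cfg$bandpass[2], cfg$fs)
  filt <- .betatrace_cache[[key]]
  if (is.null(filt)) {
    filt <- signal::butter(cfg$butter_order, cfg$bandpass / (cfg$fs / 2),
                           type = "pass")
    .betatrace_cache[[key]] <- filt
  }
  filt
}
.betatrace_cache <- new.env(parent = emptyenv())

# Zero-phase filtering with odd-reflection end padding (the standard remedy
# for forward-backward edge transients on finite epochs): the signal is
# extended by its point-reflection about each endpoint, filtered both ways,
# and the extension trimmed. The pad must cover the slow settling of the
# 3 Hz high-pass edge (~fs/3 samples), so a quarter-epoch pad is used.
filtfilt_padded <- function(filt, x, pad = 256) {
  n <- length(x)
  pad <- min(pad, n - 1)
  front <- 2 * x[1] - x[(pad + 1):2]
  back <- 2 * x[n] - x[(n - 1):(n - pad)]
  y <- signal::filtfilt(filt, c(front, x, back))
  y[(pad + 1):(pad + n)]
}

#' Per-epoch preprocessing: bandpass, detrend, z-score
#'
#' Applies, in order: a zero-phase (forward-backward) Butterworth bandpass,
#' linear detrending, and z-scoring (the epoch ends with mean 0 and standard
#' deviation 1). Z-scoring equalizes the energy of every epoch, so isolated
#' high-energy noise epochs cannot dominate the session summary. The Tukey
#' taper is *not* applied here: it belongs to each Welch segment (see
#' [welch_psd()]).
#'
#' @param epoch_uv Numeric vector, one accepted epoch in microvolts.
#' @param cfg A [processing_config()].
#' @return The processed numeric vector, with attribute `degenerate = TRUE`
#'   when the filtered epoch has (numerically) zero variance, in which case
#'   the values are all zero rather than divided by zero and the epoch must
#'   be discarded as degenerate.
#' @export
preprocess_epoch <- function(epoch_uv, cfg = processing_config()) {
  if (length(epoch_uv) != cfg$epoch_len) {
    abort(paste0("Epoch has ", length(epoch_uv), " samples; expected ",
                 cfg$epoch_len, "."))
  }
  if (sd(epoch_uv) < 1e-12) {
    y <- rep(0, length(epoch_uv))
    attr(y, "degenerate") <- TRUE
    return(y)
  }
  filt <- butter_for(cfg)
  y <- filtfilt_padded(filt, epoch_uv)
  y <- detrend_linear(y)
  s <- sd(y)
  if (!is.finite(s) || s < 1e-12) {
    y <- rep(0, length(y))
    attr(y, "degenerate") <- TRUE
    return(y)
  }
  y <- (y - mean(y)) / s
  attr(y, "degenerate") <- FALSE
  y
}

#' Welch power spectral density of a processed epoch
#'
#' Averages modified periodograms over Tukey-tapered segments with the
#' configured overlap, one-sided, scaled so that the integral of the PSD
#' over frequency equals the signal variance (up to taper leakage).
#'
#' @param x Processed epoch (numeric vector of length `cfg$epoch_len`, e.g.
#'   from [preprocess_epoch()]).
#' @param cfg A [processing_config()].
#' @param epoch_index Optional epoch index stored on the result.
#' @return A tibble of class `beta_psd` with columns `freq` (Hz, ascending,
#'   spacing `fs / welch_segment_len`) and `power` (non-negative), plus
#'   attributes `df` (bin width) and `epoch_index`.
#' @examples
#' x <- preprocess_epoch(sin(2 * pi * 20 * (0:1023) / 512) * 10 + rnorm(1024))
#' p <- welch_psd(x)
#' p$freq[which.max(p$power)] # 20
#' @export
welch_psd <- function(x, cfg = processing_config(), epoch_index = NA_integer_) {
  L <- cfg$welch_segment_len
  n <- length(x)
  if (L > n) abort("Welch segment length exceeds the epoch length.")
  step <- round(L * (1 - cfg$welch_overlap))
  starts <- seq(1, n - L + 1, by = step)
  w <- tukey_window(L, cfg$tukey_fraction)
  scale <- cfg$fs * sum(w^2)
  nf <- L %/% 2 + 1
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + L - 1)] * w
    X <- fft(seg)[seq_len(nf)]
    acc <- acc + (Mod(X)^2) / scale
  }
  p <- acc / length(starts)
  # one-sided: double everything except DC and (for even L) Nyquist
  dbl <- rep(2, nf)
  dbl[1] <- 1
  if (L %% 2 == 0) dbl[nf] <- 1
  p <- p * dbl
  out <- tibble::new_tibble(
    list(freq = (seq_len(nf) - 1) * cfg$fs / L, power = p), nrow = nf
  )
  class(out) <- c("beta_psd", class(out))
  attr(out, "df") <- cfg$fs / L
  attr(out, "epoch_index") <- epoch_index
  out
}

#' Integrated band power of a PSD
#'
#' Sums `power * bin_width` over the bins whose center frequency falls in
#' the band. The headline beta statistic uses the closed interval
#' \[12, 30\] Hz; `left_closed = FALSE` gives the half-open variant used to
#' partition adjacent bands without double counting.
#'
#' @param psd A `beta_psd` tibble from [welch_psd()].
#' @param band Length-2 numeric band in Hz (default the beta band 12-30).
#' @param left_closed Include the lower edge (default `TRUE`).
#' @return Scalar band power.
#' @export
band_power <- function(psd, band = c(12, 30), left_closed = TRUE) {
  df <- attr(psd, "df") %||% diff(psd$freq[1:2])
  sel <- if (left_closed) {
    psd$freq >= band[1] & psd$freq <= band[2]
  } else {
    psd$freq > band[1] & psd$freq <= band[2]
  }
  if (!any(sel)) abort("No PSD bins fall inside the requested band.")
  sum(psd$power[sel]) * df
}

#' Run the full per-epoch chain over an epoch table
#'
#' For each epoch: convert vendor units to microvolts, clip to the physical
#' amplitude range (counting clipped samples), apply the artifact gate, then
#' bandpass/detrend/z-score, Welch PSD, and beta band power. Epochs outside
#' the analysis mask can be skipped (`status = "masked"`), since they
#' contribute nothing downstream.
#'
#' @param epochs Epoch tibble from [assemble_epochs()] (columns
#'   `subject_id`, `epoch_index`, `start_s`, `raw`).
#' @param cfg A [processing_config()].
#' @param annotation Optional [session_annotation()]; when supplied, epochs
#'   not fully inside a `video` segment are marked `"masked"` and not
#'   processed further.
#' @return A tibble with columns `subject_id`, `epoch_index`, `start_s`,
#'   `status` (`"ok"`, `"artifact"`, `"degenerate"` or `"masked"`),
#'   `n_clipped` and `beta_power` (`NA` unless status is `"ok"`).
#' @export
process_epochs <- function(epochs, cfg = processing_config(),
                           annotation = NULL) {
  n <- nrow(epochs)
  status <- character(n)
  n_clipped <- integer(n)
  beta <- rep(NA_real_, n)
  in_mask <- if (is.null(annotation)) rep(TRUE, n) else {
    epoch_in_video(epochs$start_s, cfg$epoch_len / cfg$fs, annotation)
  }
  lo <- cfg$amplitude_range_uV[1]
  hi <- cfg$amplitude_range_uV[2]
  for (i in seq_len(n)) {
    if (!in_mask[i]) {
      status[i] <- "masked"
      next
    }
    uv <- raw_to_uv(epochs$raw[[i]])
    n_clipped[i] <- sum(uv < lo | uv > hi)
    uv <- pmin(pmax(uv, lo), hi)
    if (is_artifact(uv, cfg$artifact_threshold_uV, cfg$epoch_len)) {
      status[i] <- "artifact"
      next
    }
    x <- preprocess_epoch(uv, cfg)
    if (isTRUE(attr(x, "degenerate"))) {
      status[i] <- "degenerate"
      next
    }
    status[i] <- "ok"
    beta[i] <- band_power(welch_psd(x, cfg, epochs$epoch_index[i]),
                          cfg$beta_band)
  }
  tibble::new_tibble(list(
    subject_id = epochs$subject_id,
    epoch_index = epochs$epoch_index,
    start_s = epochs$start_s,
    status = status,
    n_clipped = n_clipped,
    beta_power = beta
  ), nrow = n)
}

# TRUE for epochs lying fully inside a video segment: both the start time
# and the end time of the half-open window [start, start + dur) are within
# the segment.
epoch_in_video <- function(start_s, dur_s, annotation) {
  video <- annotation[annotation$label == "video", , drop = FALSE]
  vapply(start_s, function(s) {
    any(s >= video$start_s & (s + dur_s) <= video$end_s)
  }, logical(1))
}

#' Summarize one subject's session
#'
#' Keeps only epochs fully inside video-labeled segments, drops artifact and
#' degenerate epochs, and summarizes per-epoch beta power over the kept set
#' (mean by default; see [processing_config()]). A subject with zero kept
#' epochs is flagged invalid and excluded from cohort normalization.
#'
#' @param processed Epoch table from [process_epochs()] for one subject. If
#'   it was produced without the annotation, the mask is applied here.
#' @param annotation A [session_annotation()].
#' @param cfg A [processing_config()].
#' @return One-row tibble: `subject_id`, `n_epochs_total`,
#'   `n_excluded_by_mask`, `n_rejected_artifact`, `n_rejected_degenerate`,
#'   `n_kept`, `total_mean_beta`, `valid`. The four count columns plus
#'   `n_kept` sum to `n_epochs_total`.
#' @export
summarize_subject <- function(processed, annotation,
                              cfg = processing_config()) {
  stopifnot(length(unique(processed$subject_id)) <= 1)
  dur <- cfg$epoch_len / cfg$fs
  in_mask <- epoch_in_video(processed$start_s, dur, annotation)
  masked <- !in_mask | processed$status == "masked"
  art <- in_mask & processed$status == "artifact"
  deg <- in_mask & processed$status == "degenerate"
  kept <- in_mask & processed$status == "ok"
  total_beta <- if (any(kept)) {
    switch(cfg$summary_stat,
           mean = mean(processed$beta_power[kept]),
           sum = sum(processed$beta_power[kept]))
  } else NA_real_
  valid <- any(kept)
  if (!valid) {
    warn(paste0("Subject '", processed$subject_id[1] %||% "?",
                "' has no accepted in-mask epochs; summary flagged invalid."))
  }
  tibble(
    subject_id = processed$subject_id[1] %||% NA_character_,
    n_epochs_total = nrow(processed),
    n_excluded_by_mask = sum(masked),
    n_rejected_artifact = sum(art),
    n_rejected_degenerate = sum(deg),
    n_kept = sum(kept),
    total_mean_beta = total_beta,
    valid = valid
  )
}

#' Min-max normalize subject summaries across a cohort
#'
#' Adds `normalized_beta = (x - min) / (max - min)` over the valid subjects'
#' `total_mean_beta`, so the lowest-beta subject maps to 0 and the highest
#' to 1; the map is order-preserving. Invalid subjects get `NA`.
#'
#' @param summaries Tibble of stacked [summarize_subject()] rows.
#' @return The input with a `normalized_beta` column appended.
#' @export
normalize_cohort <- function(summaries) {
  valid <- summaries$valid & is.finite(summaries$total_mean_beta)
  if (sum(valid) < 2) {
    abort("Cohort normalization needs at least 2 valid subjects.")
  }
  x <- summaries$total_mean_beta[valid]
  if (max(x) == min(x)) {
    abort("All valid subjects have identical total mean beta; min-max normalization is undefined.")
  }
  out <- summaries
  out$normalized_beta <- ifelse(
    valid,
    (summaries$total_mean_beta - min(x)) / (max(x) - min(x)),
    NA_real_
  )
  out
}

#' Process one subject end to end: epochs from a trace, chain, summary
#'
#' Convenience composition used by the pipeline: packetizes nothing (the
#' trace is epoched directly on the unbroken sample clock), runs
#' [process_epochs()] under the annotation mask and returns both the epoch
#' table and the one-row summary.
#'
#' @param trace Trace tibble (`raw_value` column) for one subject.
#' @param subject_id Subject identifier.
#' @param annotation A [session_annotation()].
#' @param cfg A [processing_config()].
#' @return List with `epochs` (processed epoch table) and `summary`
#'   (one-row tibble).
#' @export
process_subject <- function(trace, subject_id, annotation,
                            cfg = processing_config()) {
  samples <- if (is.data.frame(trace)) trace$raw_value else as.integer(trace)
  n_ep <- length(samples) %/% cfg$epoch_len
  epochs <- tibble::new_tibble(list(
    subject_id = rep(subject_id, n_ep),
    epoch_index = seq_len(n_ep) - 1L,
    start_s = (seq_len(n_ep) - 1L) * cfg$epoch_len / cfg$fs,
    raw = purrr::map(seq_len(n_ep), function(i) {
      samples[((i - 1L) * cfg$epoch_len + 1L):(i * cfg$epoch_len)]
    })
  ), nrow = n_ep)
  processed <- process_epochs(epochs, cfg, annotation)
  list(epochs = processed,
       summary = summarize_subject(processed, annotation, cfg))
}

#' Epoch-level beta power time series plot
#'
#' @param processed Epoch table from [process_epochs()].
#' @return A ggplot: beta power against epoch start time, rejected epochs
#'   marked by status.
#' @export
plot_beta_timeseries <- function(processed) {
  ggplot2::ggplot(processed,
                  ggplot2::aes(x = .data$start_s, y = .data$beta_power)) +
    ggplot2::geom_line(data = function(d) d[d$status == "ok", ],
                       color = "grey40") +
    ggplot2::geom_point(ggplot2::aes(color = .data$status), size = 1.5) +
    ggplot2::labs(x = "Epoch start (s)", y = "Beta band power",
                  color = "Epoch status") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.beta_psd <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$freq, y = .data$power)) +
    ggplot2::geom_line() +
    ggplot2::annotate("rect", xmin = 12, xmax = 30, ymin = -Inf, ymax = Inf,
                      alpha = 0.08, fill = "blue") +
    ggplot2::labs(x = "Frequency (Hz)", y = "PSD",
                  title = "Welch PSD (beta band shaded)") +
    ggplot2::theme_minimal()
}
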