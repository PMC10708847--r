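# Independent brute-force oracles used across tests.

# Mann-Whitney U of group a vs b: count of (a, b) pairs won by a, ties at 1/2.
brute_u <- function(a, b) {
  sum(outer(a, b, function(x, y) (x > y) + 0.5 * (x == y)))
}

# AUC as the fraction of (positive, negative) pairs ranked correctly,
# ties at 1/2.
brute_auc <- function(prob, pos) {
  p <- prob[pos]
  q <- prob[!pos]
  mean(outer(p, q, function(x, y) (x > y) + 0.5 * (x == y)))
}

# Direct single-taper periodogram: Tukey(r)-windowed, one-sided, scaled to
# integrate to the signal variance.
direct_periodogram <- function(x, fs, taper_fraction = 0.15) {
  n <- length(x)
  w <- betatrace:::tukey_window(n, taper_fraction)
  X <- fft(x * w)[seq_len(n %/% 2 + 1)]
  p <- Mod(X)^2 / (fs * sum(w^2))
  dbl <- rep(2, length(p))
  dbl[1] <- 1
  if (n %% 2 == 0) dbl[length(p)] <- 1
  list(freq = (seq_along(p) - 1) * fs / n, power = p * dbl)
}

# A bare sinusoid epoch in microvolts.
sine_epoch <- function(freq, amp = 10, fs = 512, n = 1024) {
  amp * sin(2 * pi * freq * (seq_len(n) - 1) / fs)
}

# Epoch table in the shape produced by assemble_epochs()/direct epoching.
raw_epoch_table <- function(raw_list, fs = 512, subject_id = "S001") {
  tibble::tibble(
    subject_id = subject_id,
    epoch_index = seq_along(raw_list) - 1L,
    start_s = (seq_along(raw_list) - 1L) * length(raw_list[[1]]) / fs,
    raw = raw_list
  )
}

# Annotation with a single all-session video segment.
video_annotation <- function(end_s) {
  session_annotation(data.frame(label = "video", start_s = 0, end_s = end_s))
}
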