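#' Split a raw trace into sequence-numbered sample packets
#'
#' Emulates the Bluetooth-to-main-server transport, which forwards raw
#' samples in IP packets. Packets carry consecutive 0-based sequence numbers;
#' the last packet may be short. The default packet size of 512 samples is
#' one second of signal.
#'
#' @param trace Trace tibble with a `raw_value` column (see
#'   [generate_trace()]), or a bare integer vector.
#' @param subject_id Subject identifier stamped on every packet.
#' @param packet_size Samples per packet (>= 1).
#'
#' @return A tibble with columns `subject_id`, `seq` and `samples`
#'   (a list-column of integer vectors). An empty trace yields zero rows.
#' @examples
#' pk <- packetize(generate_trace(signal_spec(2, pink_gain = 3)), "S001", 256)
#' nrow(pk) # 4
#' @export
packetize <- function(trace, subject_id = "S001", packet_size = 512) {
  if (packet_size < 1) abort("`packet_size` must be at least 1.")
  samples <- if (is.data.frame(trace)) trace$raw_value else as.integer(trace)
  n <- length(samples)
  if (n == 0) {
    return(tibble(subject_id = character(), seq = integer(),
                  samples = list()))
  }
  starts <- seq(1, n, by = packet_size)
  tibble(
    subject_id = subject_id,
    seq = seq_along(starts) - 1L,
    samples = purrr::map(starts, function(s) {
      samples[s:min(s + packet_size - 1, n)]
    })
  )
}

#' Reassemble the sample stream carried by a packet sequence
#'
#' @param packets Packet tibble from [packetize()].
#' @return Integer vector: the concatenation of the packets' samples in
#'   sequence order.
#' @export
depacketize <- function(packets) {
  ord <- order(packets$seq)
  as.integer(unlist(packets$samples[ord], use.names = FALSE))
}

#' Admit clients to an acquisition server of fixed capacity
#'
#' One acquisition-server instance multiplexes at most `capacity` headsets
#' (four in the deployed platform); surplus connection attempts are refused,
#' which is a normal outcome rather than an error.
#'
#' @param requested Character vector of client ids, or a count (ids are then
#'   generated as `client1..clientN`).
#' @param capacity Maximum concurrent clients per server instance.
#'
#' @return A tibble with columns `client`, `accepted` (logical) and `reason`
#'   (`"ok"` or `"capacity"`), one row per requested client in arrival order.
#' @examples
#' accept_clients(5)
#' @export
accept_clients <- function(requested, capacity = 4) {
  if (length(requested) == 1 && is.numeric(requested)) {
    if (requested < 0) abort("`requested` must be non-negative.")
    requested <- if (requested == 0) character() else {
      paste0("client", seq_len(requested))
    }
  }
  n <- length(requested)
  tibble(
    client = as.character(requested),
    accepted = seq_len(n) <= capacity,
    reason = ifelse(seq_len(n) <= capacity, "ok", "capacity")
  )
}

#' Assemble contiguous fixed-length epochs from a packet stream
#'
#' Consumes a single subject's packets in sequence order and emits
#' consecutive, non-overlapping epochs of exactly `epoch_len` samples (two
#' seconds at 512 Hz). A gap in the sequence numbers invalidates the window
#' under construction: the pending samples are discarded (zero-filling would
#' silently bias the PSD downward) and assembly resumes at the next packet
#' boundary. Discards are logged in the result's `discard_log` attribute.
#'
#' @param packets Packet tibble from [packetize()] for a single subject.
#' @param epoch_len Samples per epoch (default 1024).
#' @param fs Sampling rate used to compute epoch start times (default 512).
#'
#' @return A tibble with columns `subject_id`, `epoch_index` (0-based),
#'   `start_s` (epoch start time assuming an unbroken 1/fs clock from the
#'   session start) and `raw` (list-column of `epoch_len`-sample integer
#'   vectors). Attributes: `n_discarded_windows`, `pending` (samples left in
#'   the unfinished window) and `discard_log` (tibble of gap events).
#' @examples
#' tr <- generate_trace(signal_spec(4, pink_gain = 3))
#' ep <- assemble_epochs(packetize(tr))
#' nrow(ep) # 2
#' @export
assemble_epochs <- function(packets, epoch_len = 1024, fs = 512) {
  if (epoch_len < 1) abort("`epoch_len` must be at least 1.")
  if (nrow(packets) == 0) {
    out <- tibble(subject_id = character(), epoch_index = integer(),
                  start_s = numeric(), raw = list())
    attr(out, "n_discarded_windows") <- 0L
    attr(out, "pending") <- 0L
    attr(out, "discard_log") <- tibble(after_seq = integer(),
                                       resumed_seq = integer())
    return(out)
  }
  if (length(unique(packets$subject_id)) > 1) {
    abort("`assemble_epochs()` expects packets for a single subject.")
  }
  if (anyDuplicated(packets$seq)) {
    dup <- packets$seq[duplicated(packets$seq)][1]
    abort(paste0("Duplicate packet seq ", dup, " for subject '",
                 packets$subject_id[1], "'."))
  }
  packets <- packets[order(packets$seq), ]
  subject <- packets$subject_id[1]
  sizes <- lengths(packets$samples)
  # Absolute sample position of each packet start, from its seq number and
  # the nominal packet size (the size of packet 0); a short packet can only
  # legitimately be the final one.
  nominal <- sizes[1]
  pos <- packets$seq * nominal

  epoch_raw <- list()
  epoch_start <- numeric()
  pending <- integer()
  pending_start <- 0 # absolute sample index where `pending` begins
  expected_pos <- pos[1]
  discards <- list()
  n_discarded <- 0L

  for (i in seq_len(nrow(packets))) {
    if (pos[i] != expected_pos) {
      if (length(pending) > 0) {
        n_discarded <- n_discarded + 1L
        discards[[length(discards) + 1]] <- tibble(
          after_seq = packets$seq[i - 1], resumed_seq = packets$seq[i]
        )
      }
      pending <- integer()
    } else if (i > 1 && sizes[i - 1] != nominal) {
      abort(paste0("Short packet seq ", packets$seq[i - 1],
                   " is not the final packet for subject '", subject, "'."))
    }
    if (length(pending) == 0) pending_start <- pos[i]
    pending <- c(pending, packets$samples[[i]])
    expected_pos <- pos[i] + nominal
    while (length(pending) >= epoch_len) {
      epoch_raw[[length(epoch_raw) + 1]] <- as.integer(pending[seq_len(epoch_len)])
      epoch_start[length(epoch_raw)] <- pending_start / fs
      pending <- pending[-seq_len(epoch_len)]
      pending_start <- pending_start + epoch_len
    }
  }
  out <- tibble::new_tibble(list(
    subject_id = rep(subject, length(epoch_raw)),
    epoch_index = seq_along(epoch_raw) - 1L,
    start_s = epoch_start,
    raw = epoch_raw
  ), nrow = length(epoch_raw))
  attr(out, "n_discarded_windows") <- n_discarded
  attr(out, "pending") <- length(pending)
  attr(out, "discard_log") <- if (length(discards)) {
    dplyr::bind_rows(discards)
  } else tibble(after_seq = integer(), resumed_seq = integer())
  out
}

#' Serialize or replay a packet stream as JSON lines
#'
#' One packet per line (`subject_id`, `seq`, `samples`), a convenient
#' plain-text replay fixture format.
#'
#' @param packets Packet tibble from [packetize()].
#' @param path Output/input path.
#' @return `write_packets_jsonl()` returns `path` invisibly;
#'   `read_packets_jsonl()` returns a packet tibble.
#' @export
write_packets_jsonl <- function(packets, path) {
  lines <- purrr::map_chr(seq_len(nrow(packets)), function(i) {
    jsonlite::toJSON(
      list(subject_id = packets$subject_id[i], seq = packets$seq[i],
           samples = packets$samples[[i]]),
      auto_unbox = TRUE
    )
  })
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_packets_jsonl
#' @export
read_packets_jsonl <- function(path) {
  lines <- readLines(path)
  rows <- purrr::map(lines, function(l) jsonlite::fromJSON(l))
  tibble(
    subject_id = purrr::map_chr(rows, "subject_id"),
    seq = purrr::map_int(rows, function(r) as.integer(r$seq)),
    samples = purrr::map(rows, function(r) as.integer(r$samples))
  )
}
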