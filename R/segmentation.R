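# Segmentation: event partition of a recording and fixed 2560-sample
# (10 s at 256 Hz) non-overlapping windows within each event.
#
# Event layout (0-based half-open sample indices, T = total duration):
#   s1 [0, 180 s), m1 [180, 300 s), s2 [300, 480 s), m2 [480, 600 s),
#   m3 [T - 120 s, T), s3 [600 s, T - 120 s)   -- s3 absorbs the remainder.

FIXED_PREFIX_S <- 600 # s1 + m1 + s2 + m2
M3_S <- 120
WINDOW_SAMPLES <- 2560L

#' Read a recording from CSV
#'
#' Expects the per-session CSV layout written by [write_recording()]:
#' a `timestamp_s` column plus one column per channel (`TP9, AF7, AF8, TP10`).
#' Timestamps must be monotone with a constant 1/256 s step (within
#' tolerance).
#'
#' @param path CSV path.
#' @param subject_id,session_index Metadata to attach (parsed from the file
#'   name `<subject>_session<k>.csv` when omitted).
#' @return An `eeg_recording`.
#' @export
read_recording <- function(path, subject_id = NULL, session_index = NULL) {
  df <- read.csv(path, check.names = FALSE)
  if (!"timestamp_s" %in% names(df)) stop_ef("parse error: missing 'timestamp_s' column")
  missing <- setdiff(eeg_channels(), names(df))
  if (length(missing)) {
    stop_ef("parse error: missing channel column(s): %s", paste(missing, collapse = ", "))
  }
  ts <- df$timestamp_s
  if (length(ts) < 2L) stop_ef("parse error: recording has fewer than 2 samples")
  dt <- diff(ts)
  if (any(dt <= 0)) stop_ef("parse error: non-monotone timestamps")
  if (any(abs(dt - 1 / EEG_FS) > 1e-6)) {
    stop_ef("parse error: sampling interval not constant at 1/%d s", EEG_FS)
  }
  if (is.null(subject_id) || is.null(session_index)) {
    m <- regmatches(basename(path),
                    regexec("^(.+)_session([0-9]+)\\.csv$", basename(path)))[[1]]
    if (length(m) == 3L) {
      if (is.null(subject_id)) subject_id <- m[2]
      if (is.null(session_index)) session_index <- as.integer(m[3])
    } else {
      if (is.null(subject_id)) subject_id <- "unknown"
      if (is.null(session_index)) session_index <- NA_integer_
    }
  }
  channels <- lapply(eeg_channels(), function(ch) as.numeric(df[[ch]]))
  names(channels) <- eeg_channels()
  structure(
    list(subject_id = subject_id, session_index = as.integer(session_index),
         sampling_rate = EEG_FS, total_duration_s = nrow(df) / EEG_FS,
         channels = channels),
    class = "eeg_recording"
  )
}

#' Partition a recording into its six labelled events
#'
#' The first 600 s are the fixed-duration events s1 (180 s), m1 (120 s),
#' s2 (180 s), m2 (120 s); the final 120 s are m3 (taken from the very end of
#' the signal); everything between (after m2 until m3) is the variable-length
#' mental task s3. A recording shorter than 720 s is rejected; exactly 720 s
#' yields an empty (flagged) s3 range.
#'
#' @param recording An `eeg_recording` (or any list with `sampling_rate` and
#'   equal-length `channels`).
#' @return data.frame with columns `event`, `start_sample`, `end_sample`
#'   (0-based, half-open), jointly covering `[0, T x 256)` without overlap.
#' @export
partition_events <- function(recording) {
  fs <- recording$sampling_rate
  n <- unique(vapply(recording$channels, length, integer(1)))
  if (length(n) != 1L) stop_ef("partition error: channels have unequal lengths")
  need <- (FIXED_PREFIX_S + M3_S) * fs
  if (n < need) {
    stop_ef("partition error: recording is %.1f s, needs >= %d s", n / fs,
            FIXED_PREFIX_S + M3_S)
  }
  fixed <- c(s1 = 180, m1 = 120, s2 = 180, m2 = 120)
  ends <- cumsum(fixed) * fs
  starts <- c(0, ends[-4])
  s3_start <- FIXED_PREFIX_S * fs
  s3_end <- n - M3_S * fs
  if (s3_end == s3_start) {
    ef_log("info", "recording %s/%s: empty s3 range (total duration exactly 720 s)",
           recording$subject_id, recording$session_index)
  }
  data.frame(
    event = c(names(fixed), "s3", "m3"),
    start_sample = as.integer(c(starts, s3_start, s3_end)),
    end_sample = as.integer(c(ends, s3_end, n)),
    stringsAsFactors = FALSE
  )
}

#' Cut a sample vector into fixed non-overlapping windows
#'
#' `floor(length / window)` consecutive windows; a trailing remainder shorter
#' than `window` is discarded. An empty input yields an empty list.
#'
#' @param samples Numeric vector (one channel within one event).
#' @param window Window length in samples (default 2560 = 10 s at 256 Hz).
#' @return List of numeric vectors of length `window`; names are the 0-based
#'   `window_index`.
#' @export
segment_event <- function(samples, window = WINDOW_SAMPLES) {
  check_number(window, "window", lower = 1)
  window <- as.integer(window)
  k <- length(samples) %/% window
  if (k == 0L) return(structure(list(), names = character(0)))
  out <- lapply(seq_len(k) - 1L, function(i) samples[(i * window + 1L):((i + 1L) * window)])
  names(out) <- as.character(seq_len(k) - 1L)
  out
}

#' Segment a whole recording into windows per channel and event
#'
#' Convenience wrapper combining [partition_events()] and [segment_event()].
#' Window boundaries are channel-independent by construction.
#'
#' @param recording An `eeg_recording`.
#' @param window Window length in samples.
#' @param preprocess Optional function applied to each channel's full sample
#'   vector before windowing (pass-through hook; no filtering is applied by
#'   default).
#' @param windows_per_event Optional cap on the number of windows kept per
#'   event (the first `k`); `Inf` (default) keeps all. A compute-budget
#'   subsample for desk-scale runs - see the vignette.
#' @param events Optional subset of events to keep (default: all six).
#' @return data.frame with columns `subject`, `session`, `channel`, `event`,
#'   `window_index`, `start_sample`, `end_sample` and a list-column `samples`.
#' @export
segment_recording <- function(recording, window = WINDOW_SAMPLES,
                              preprocess = NULL, windows_per_event = Inf,
                              events = NULL) {
  ranges <- partition_events(recording)
  if (!is.null(events)) ranges <- ranges[ranges$event %in% events, , drop = FALSE]
  rows <- list()
  for (ch in names(recording$channels)) {
    x <- recording$channels[[ch]]
    if (!is.null(preprocess)) x <- preprocess(x)
    for (r in seq_len(nrow(ranges))) {
      ev <- ranges$event[r]
      lo <- ranges$start_sample[r]; hi <- ranges$end_sample[r]
      segs <- if (hi > lo) segment_event(x[(lo + 1L):hi], window) else list()
      if (is.finite(windows_per_event) && length(segs) > windows_per_event) {
        segs <- segs[seq_len(windows_per_event)]
      }
      if (!length(segs)) next
      idx <- as.integer(names(segs))
      rows[[length(rows) + 1L]] <- data.frame(
        subject = recording$subject_id, session = recording$session_index,
        channel = ch, event = ev, window_index = idx,
        start_sample = lo + idx * as.integer(window),
        end_sample = lo + (idx + 1L) * as.integer(window),
        stringsAsFactors = FALSE
      )
      rows[[length(rows)]]$samples <- I(unname(segs))
    }
  }
  if (!length(rows)) {
    return(data.frame(subject = character(0), session = integer(0),
                      channel = character(0), event = character(0),
                      window_index = integer(0), start_sample = integer(0),
                      end_sample = integer(0)))
  }
  do.call(rbind, rows)
}

#' Write a segment index (without samples) as CSV
#'
#' @param segments Output of [segment_recording()].
#' @param path CSV path.
#' @return Invisibly, `path`.
#' @export
write_segment_index <- function(segments, path) {
  cols <- c("subject", "session", "channel", "event", "window_index",
            "start_sample", "end_sample")
  write.csv(segments[, cols], path, row.names = FALSE)
  invisible(path)
}
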