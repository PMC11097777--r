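#' Continuous multichannel EEG recording
#'
#' A channels x samples amplitude matrix (microvolts) with a sampling rate
#' and an ordered event list. Event sample indices are 1-based (R
#' convention) and must be strictly increasing.
#'
#' @param data Numeric matrix, channels x samples.
#' @param sampling_rate Sampling rate in Hz.
#' @param events Data frame with columns `sample` (1-based index) and `label`
#'   (0 = non-target, 1 = target); may have zero rows.
#' @param channel_ids Optional ordered channel identifiers (default 1..n).
#' @return Object of class `continuous_recording`.
#' @export
continuous_recording <- function(data, sampling_rate, events,
                                 channel_ids = seq_len(nrow(data))) {
  if (sampling_rate <= 0) stop("sampling_rate must be positive")
  data <- as.matrix(data)
  if (is.null(events) || nrow(events) == 0L)
    events <- data.frame(sample = integer(0), label = integer(0))
  if (!all(c("sample", "label") %in% names(events)))
    stop("events needs columns 'sample' and 'label'")
  if (nrow(events) > 1L && any(diff(events$sample) <= 0))
    stop("event sample indices must be strictly increasing")
  if (nrow(events) > 0L &&
      (any(events$sample < 1L) || any(events$sample > ncol(data))))
    stop("event sample indices outside the recording")
  if (length(channel_ids) != nrow(data))
    stop("channel_ids length must equal the channel count")
  structure(list(data = data, sampling_rate = sampling_rate,
                 events = events, channel_ids = channel_ids),
            class = "continuous_recording")
}

#' @export
print.continuous_recording <- function(x, ...) {
  cat("Continuous recording:", nrow(x$data), "channels x", ncol(x$data),
      "samples @", x$sampling_rate, "Hz;", nrow(x$events), "events (",
      sum(x$events$label == 1L), "targets )\n")
  invisible(x)
}

#' Band-pass filter specification
#'
#' @param low_hz,high_hz Passband edges, `0 < low < high < rate/2`.
#' @param order Butterworth order (applied forward-backward when
#'   `zero_phase`, doubling the effective order).
#' @param zero_phase Apply forward-backward for zero group delay (default;
#'   preserves P300 latency).
#' @return Object of class `filter_spec`.
#' @export
filter_spec <- function(low_hz = 2, high_hz = 30, order = 4L,
                        zero_phase = TRUE) {
  if (low_hz <= 0 || high_hz <= low_hz) stop("need 0 < low_hz < high_hz")
  structure(list(low_hz = low_hz, high_hz = high_hz, order = as.integer(order),
                 zero_phase = isTRUE(zero_phase)),
            class = "filter_spec")
}

#' Channel indices of the 62-electrode montage
#'
#' The reference montage keeps electrodes 1-32, 34-42 and 44-64 out of 64
#' (electrodes 33 and 43 are dropped).
#' @export
default_keep_channels <- function() c(1:32, 34:42, 44:64)

#' Select (and reorder) channels of a recording
#'
#' @param recording A [continuous_recording()].
#' @param keep 1-based channel indices, kept in the given order; the default
#'   reduces a 64-channel montage to the reference 62 channels.
#' @return The reduced recording.
#' @export
select_channels <- function(recording, keep = default_keep_channels()) {
  stopifnot(inherits(recording, "continuous_recording"))
  bad <- keep[keep < 1L | keep > nrow(recording$data)]
  if (length(bad))
    stop("unknown channel index: ", paste(bad, collapse = ", "))
  recording$data <- recording$data[keep, , drop = FALSE]
  recording$channel_ids <- recording$channel_ids[keep]
  recording
}

#' Zero-phase Butterworth band-pass
#'
#' Filters each channel independently with a Butterworth band-pass designed
#' by [signal::butter()]; with `zero_phase` the filter runs forward and
#' backward ([signal::filtfilt()]), cancelling group delay. Filtering is
#' linear and shape-preserving. Filter before epoching: filtering extracted
#' epochs directly incurs edge artifacts (a warning is issued if epochs are
#' passed through [bandpass()] via [simulate_subject()]'s internals or
#' user code on short segments).
#'
#' @param recording A [continuous_recording()].
#' @param spec A [filter_spec()].
#' @return The filtered recording.
#' @export
bandpass <- function(recording, spec = filter_spec()) {
  stopifnot(inherits(recording, "continuous_recording"),
            inherits(spec, "filter_spec"))
  nyq <- recording$sampling_rate / 2
  if (spec$high_hz >= nyq)
    stop("upper passband edge (", spec$high_hz,
         " Hz) must lie below the Nyquist frequency (", nyq, " Hz)")
  bf <- signal::butter(spec$order, c(spec$low_hz, spec$high_hz) / nyq,
                       type = "pass")
  apply_fn <- if (spec$zero_phase)
    function(x) signal::filtfilt(bf, x)
  else
    function(x) as.numeric(signal::filter(bf, x))
  recording$data <- t(apply(recording$data, 1L, apply_fn))
  recording
}

#' Labelled single-trial epochs
#'
#' The universal currency between pipeline stages: a
#' `(trials, channels, samples)` amplitude array with 0/1 labels.
#'
#' @param epochs Numeric 3-d array, trials x channels x samples.
#' @param labels 0/1 vector, one per trial.
#' @param sampling_rate Hz.
#' @return Object of class `epoch_set`.
#' @export
epoch_set <- function(epochs, labels, sampling_rate) {
  d <- dim(epochs)
  if (length(d) != 3L) stop("epochs must be trials x channels x samples")
  if (length(labels) != d[1L])
    stop("labels length (", length(labels), ") != trial count (", d[1L], ")")
  if (d[1L] > 0L && !all(labels %in% c(0L, 1L)))
    stop("labels must be 0 or 1")
  structure(list(epochs = epochs, labels = as.integer(labels),
                 sampling_rate = sampling_rate),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$epochs)
  cat("Epoch set:", d[1L], "trials x", d[2L], "channels x", d[3L],
      "samples @", x$sampling_rate, "Hz;", sum(x$labels == 1L),
      "targets /", sum(x$labels == 0L), "non-targets\n")
  invisible(x)
}

#' Extract stimulus-locked epochs
#'
#' Cuts one epoch per event over the half-open window
#' `[event + start, event + end)` in milliseconds, so a 0-1000 ms window at
#' 250 Hz yields exactly 250 samples starting at the event sample.
#' Overlapping windows are permitted (1 s epochs overlap at a 10 Hz stimulus
#' rate). Pure indexing: amplitudes are copied bit-exactly.
#'
#' @param recording A [continuous_recording()].
#' @param window_ms Length-2 numeric, `(start, end)` in ms, `start >= 0`.
#' @return An [epoch_set()]; zero events give a 0-trial set.
#' @export
extract_epochs <- function(recording, window_ms = c(0, 1000)) {
  stopifnot(inherits(recording, "continuous_recording"))
  if (window_ms[1L] < 0 || window_ms[2L] <= window_ms[1L])
    stop("window must satisfy 0 <= start < end")
  rate <- recording$sampling_rate
  s_off <- round(window_ms[1L] / 1000 * rate)
  n_len <- round((window_ms[2L] - window_ms[1L]) / 1000 * rate)
  nch <- nrow(recording$data)
  ev <- recording$events
  out <- array(0, c(nrow(ev), nch, n_len))
  for (i in seq_len(nrow(ev))) {
    from <- ev$sample[i] + s_off
    to <- from + n_len - 1L
    if (to > ncol(recording$data))
      stop("epoch window for event ", i, " (sample ", ev$sample[i],
           ") exceeds the recording")
    out[i, , ] <- recording$data[, from:to]
  }
  epoch_set(out, ev$label, rate)
}
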