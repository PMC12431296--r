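#' Construct a continuous multichannel EEG recording
#'
#' @param samples numeric matrix, channels x time, in microvolts.
#' @param channel_names character vector of unique 10-10 electrode labels,
#'   one per row of `samples`.
#' @param fs sampling rate in Hz (250 for the reference datasets).
#' @param events optional data.frame with columns `onset` (sample index,
#'   1-based, of the imagery cue) and `label` (class id in 0..3).
#' @return an object of class `eeg_recording`.
#' @export
eeg_recording <- function(samples, channel_names, fs = 250, events = NULL) {
  samples <- as.matrix(samples)
  if (length(channel_names) != nrow(samples))
    stop("channel_names length must match number of rows in samples")
  if (anyDuplicated(channel_names))
    stop("channel_names must be unique")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("fs must be a positive scalar")
  if (!is.null(events)) {
    events <- as.data.frame(events)
    if (!all(c("onset", "label") %in% names(events)))
      stop("events must have columns 'onset' and 'label'")
    if (any(events$onset < 1 | events$onset > ncol(samples)))
      stop("event onsets must lie within the recording")
    if (!all(events$label %in% 0:3))
      stop("event labels must be in 0..3")
  }
  structure(list(samples = samples, channel_names = as.character(channel_names),
                 fs = fs, events = events),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz, %d events\n",
              nrow(x$samples), ncol(x$samples), x$fs,
              if (is.null(x$events)) 0L else nrow(x$events)))
  invisible(x)
}

#' Construct a set of labelled EEG epochs
#'
#' @param data numeric array, trial x channel x sample, microvolts.
#' @param labels integer vector of class ids in 0..3, one per trial.
#' @param fs sampling rate in Hz.
#' @param channel_names channel labels matching dim 2 of `data`.
#' @param t_start time (s, relative to the imagery cue) of the first sample
#'   in each epoch; negative values mean the epoch starts before the cue.
#' @return an object of class `eeg_epochs`.
#' @export
eeg_epochs <- function(data, labels, fs = 250, channel_names = NULL,
                       t_start = 0) {
  if (length(dim(data)) != 3L)
    stop("data must be a trial x channel x sample array")
  labels <- as.integer(labels)
  if (length(labels) != dim(data)[1])
    stop("one label per trial required")
  if (!all(labels %in% 0:3)) stop("labels must be in 0..3")
  if (is.null(channel_names))
    channel_names <- paste0("ch", seq_len(dim(data)[2]))
  if (length(channel_names) != dim(data)[2])
    stop("channel_names length must match channel dimension")
  structure(list(data = data, labels = labels, fs = fs,
                 channel_names = as.character(channel_names),
                 t_start = t_start),
            class = "eeg_epochs")
}

#' @export
print.eeg_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<eeg_epochs> %d trials x %d channels x %d samples @ %g Hz (t0 = %gs)\n",
    d[1], d[2], d[3], x$fs, x$t_start))
  cat("  class counts:", paste(sprintf("%s=%d", MI_CLASSES,
        tabulate(x$labels + 1L, 4L)), collapse = ", "), "\n")
  invisible(x)
}

n_trials <- function(epochs) dim(epochs$data)[1]

butter_bandpass <- function(lo, hi, order, fs) {
  if (!(lo > 0 && lo < hi && hi < fs / 2))
    stop("invalid band: need 0 < lo < hi < fs/2")
  signal::butter(order, c(lo, hi) / (fs / 2), type = "pass")
}

apply_filtfilt <- function(filt, x) {
  # forward-backward (zero-phase) application along rows of a matrix
  if (is.matrix(x)) {
    t(apply(x, 1L, function(row) signal::filtfilt(filt, row)))
  } else {
    signal::filtfilt(filt, x)
  }
}

#' Zero-phase Butterworth band-pass filter
#'
#' Filters each channel with an order-`order` Butterworth band-pass design
#' applied forward and backward (zero phase), so band energies within
#' analysis windows are not phase-shifted. The 8-32 Hz default covers the
#' mu and beta rhythms that carry motor-imagery information.
#'
#' @param x an `eeg_recording`, `eeg_epochs`, channels x time matrix, or
#'   numeric vector.
#' @param lo,hi band edges in Hz; must satisfy 0 < lo < hi < fs/2.
#' @param order Butterworth prototype order (default 4).
#' @param fs sampling rate, required only for the matrix/vector methods.
#' @return object of the same shape/class, band-limited per channel.
#' @export
bandpass_filter <- function(x, lo = 8, hi = 32, order = 4, fs = NULL) {
  UseMethod("bandpass_filter")
}

#' @export
bandpass_filter.eeg_recording <- function(x, lo = 8, hi = 32, order = 4,
                                          fs = NULL) {
  filt <- butter_bandpass(lo, hi, order, x$fs)
  x$samples <- apply_filtfilt(filt, x$samples)
  x
}

#' @export
bandpass_filter.eeg_epochs <- function(x, lo = 8, hi = 32, order = 4,
                                       fs = NULL) {
  filt <- butter_bandpass(lo, hi, order, x$fs)
  d <- dim(x$data)
  for (tr in seq_len(d[1])) {
    x$data[tr, , ] <- apply_filtfilt(filt, x$data[tr, , , drop = TRUE])
  }
  x
}

#' @export
bandpass_filter.default <- function(x, lo = 8, hi = 32, order = 4, fs = NULL) {
  if (is.null(fs)) stop("fs is required for matrix/vector input")
  apply_filtfilt(butter_bandpass(lo, hi, order, fs), x)
}

#' Baseline-correct epochs against a pre-cue window
#'
#' Subtracts, per trial and channel, the mean signal over the baseline
#' window (default -200 ms to 0 ms relative to the cue) from the whole
#' epoch, removing slow pre-stimulus drift. The operation is idempotent.
#'
#' @param epochs an `eeg_epochs` object whose time axis covers the baseline
#'   window.
#' @param t0,t1 baseline window in seconds relative to the cue.
#' @return the corrected `eeg_epochs`.
#' @export
baseline_correct <- function(epochs, t0 = -0.2, t1 = 0) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  d <- dim(epochs$data)
  i0 <- round((t0 - epochs$t_start) * epochs$fs) + 1L
  i1 <- round((t1 - epochs$t_start) * epochs$fs)
  if (i0 < 1L || i1 > d[3] || i1 < i0)
    stop("baseline window lies outside the epoch")
  bl <- apply(epochs$data[, , i0:i1, drop = FALSE], c(1, 2), mean)
  epochs$data <- epochs$data - array(rep(bl, d[3]), dim = d)
  epochs
}

#' Sliding-window segmentation of a single trial
#'
#' Cuts fixed-length windows with a constant stride from the analysis span
#' of one trial. With the defaults (2 s windows, 0.04 s stride, span 1-4 s
#' post-cue at 250 Hz) this yields 26 windows per trial. Arithmetic is done
#' in integer samples to avoid floating-point fencepost errors.
#'
#' @param trial channels x samples matrix for one epoch.
#' @param fs sampling rate (Hz).
#' @param win_s window length (s), > 0.
#' @param stride_s hop between window starts (s), > 0.
#' @param t_start_s,t_end_s analysis span relative to the cue (s).
#' @param trial_t0 time of the first sample of `trial` relative to the cue.
#' @return list of channels x `round(win_s * fs)` matrices; attribute
#'   `starts` holds the window start times in seconds.
#' @export
window_segment <- function(trial, fs, win_s = 2.0, stride_s = 0.04,
                           t_start_s = 1.0, t_end_s = 4.0, trial_t0 = 0) {
  if (win_s <= 0 || stride_s <= 0) stop("win_s and stride_s must be > 0")
  if (t_end_s - t_start_s < win_s)
    stop("analysis span shorter than the window")
  trial <- as.matrix(trial)
  win_n <- as.integer(round(win_s * fs))
  stride_n <- as.integer(round(stride_s * fs))
  span_n <- as.integer(round((t_end_s - t_start_s) * fs))
  off <- as.integer(round((t_start_s - trial_t0) * fs))
  n_win <- (span_n - win_n) %/% stride_n + 1L
  if (off < 0L || off + span_n > ncol(trial))
    stop("analysis span lies outside the trial")
  out <- vector("list", n_win)
  for (w in seq_len(n_win)) {
    s0 <- off + (w - 1L) * stride_n
    out[[w]] <- trial[, (s0 + 1L):(s0 + win_n), drop = FALSE]
  }
  attr(out, "starts") <- t_start_s + (seq_len(n_win) - 1L) * stride_s
  out
}

#' Segment every epoch into labelled analysis windows
#'
#' Applies [window_segment()] to each trial and stacks the results into a
#' window-level epoch set, keeping track of which trial each window came
#' from (needed for per-trial majority voting at prediction time).
#'
#' @inheritParams window_segment
#' @param epochs an `eeg_epochs` object.
#' @return an `eeg_epochs` whose "trials" are windows, with extra fields
#'   `trial_id` (origin trial of each window) and `n_source_trials`.
#' @export
epochs_to_windows <- function(epochs, win_s = 2.0, stride_s = 0.04,
                              t_start_s = 1.0, t_end_s = 4.0) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  d <- dim(epochs$data)
  first <- window_segment(epochs$data[1, , , drop = TRUE], epochs$fs, win_s,
                          stride_s, t_start_s, t_end_s, epochs$t_start)
  n_win <- length(first)
  win_n <- ncol(first[[1]])
  out <- array(0, dim = c(d[1] * n_win, d[2], win_n))
  trial_id <- integer(d[1] * n_win)
  labels <- integer(d[1] * n_win)
  k <- 0L
  for (tr in seq_len(d[1])) {
    wins <- if (tr == 1L) first else
      window_segment(epochs$data[tr, , , drop = TRUE], epochs$fs, win_s,
                     stride_s, t_start_s, t_end_s, epochs$t_start)
    for (w in seq_len(n_win)) {
      k <- k + 1L
      out[k, , ] <- wins[[w]]
      trial_id[k] <- tr
      labels[k] <- epochs$labels[tr]
    }
  }
  res <- eeg_epochs(out, labels, epochs$fs, epochs$channel_names,
                    t_start = t_start_s)
  res$trial_id <- trial_id
  res$n_source_trials <- d[1]
  res
}

#' Extract cue-aligned epochs from a continuous recording
#'
#' @param rec an `eeg_recording` with events.
#' @param t_before seconds of pre-cue signal to keep (for the baseline).
#' @param t_after seconds of post-cue signal to keep.
#' @return an `eeg_epochs` with `t_start = -t_before`.
#' @export
extract_epochs <- function(rec, t_before = 0.5, t_after = 4.3) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (is.null(rec$events) || nrow(rec$events) == 0)
    stop("recording has no events")
  n_before <- as.integer(round(t_before * rec$fs))
  n_after <- as.integer(round(t_after * rec$fs))
  len <- n_before + n_after
  nt <- nrow(rec$events)
  data <- array(0, dim = c(nt, nrow(rec$samples), len))
  for (i in seq_len(nt)) {
    s0 <- rec$events$onset[i] - n_before
    s1 <- rec$events$onset[i] + n_after - 1L
    if (s0 < 1L || s1 > ncol(rec$samples))
      stop(sprintf("epoch %d extends outside the recording", i))
    data[i, , ] <- rec$samples[, s0:s1]
  }
  eeg_epochs(data, rec$events$label, rec$fs, rec$channel_names,
             t_start = -t_before)
}

#' Restrict epochs to a subset of channels
#'
#' @param epochs an `eeg_epochs`.
#' @param channels character vector of channel names to keep (order kept).
#' @return the reduced `eeg_epochs`.
#' @export
select_channels <- function(epochs, channels) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  idx <- match(channels, epochs$channel_names)
  if (anyNA(idx))
    stop("unknown channel(s): ",
         paste(channels[is.na(idx)], collapse = ", "))
  epochs$data <- epochs$data[, idx, , drop = FALSE]
  epochs$channel_names <- epochs$channel_names[idx]
  epochs
}
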