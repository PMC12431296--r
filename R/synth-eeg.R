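#' Standard 22-channel motor-cortex montage (10-10 labels)
#'
#' Channel order used by the 22-electrode reference recordings, mapped to
#' 10-10 system names.
#' @export
MONTAGE_22 <- c("Fz", "FC3", "FC1", "FCz", "FC2", "FC4", "C5", "C3", "C1",
                "Cz", "C2", "C4", "C6", "CP3", "CP1", "CPz", "CP2", "CP4",
                "P1", "Pz", "P2", "POz")

#' Simulation spec for synthetic motor-imagery EEG
#'
#' The generator emulates the statistical structure the pipeline assumes:
#' a 1/f (pink) noise background on every channel, ongoing mu (10 Hz) and
#' beta (20 Hz) rhythms, and class-conditional event-related
#' desynchronization (ERD) — an attenuation of the rhythm amplitude on
#' designated channels while imagery is performed. Hand classes get strong
#' contralateral ERD; leg and tongue classes get weaker midline/bilateral
#' patterns, mirroring their lower real-world separability.
#'
#' @param channels channel names (default the 22-channel montage).
#' @param fs sampling rate (Hz).
#' @param t_start,t_end epoch extent in seconds relative to the cue
#'   (covers the -200 ms baseline and the 1-4 s analysis span with margin
#'   for filter transients).
#' @param imagery interval (s) during which ERD is active.
#' @param mu_freq,beta_freq rhythm frequencies (Hz).
#' @param mu_amp,beta_amp rhythm amplitudes (microvolts).
#' @param noise_sd pink-noise standard deviation (microvolts).
#' @param erd per-class named list: each element maps channel names to
#'   attenuation fractions in `[0, 1]` (1 = rhythm fully suppressed during
#'   imagery; applied to both mu and beta rhythms).
#' @param ramp_s raised-cosine ramp length of the ERD envelope (s).
#' @return an `eeg_sim_spec`.
#' @export
eeg_sim_spec <- function(channels = MONTAGE_22, fs = 250,
                         t_start = -0.5, t_end = 4.3,
                         imagery = c(0.5, 4.3),
                         mu_freq = 10, beta_freq = 20,
                         mu_amp = 4, beta_amp = 2, noise_sd = 7,
                         erd = list(
                           "left hand"  = c(C4 = 0.40, CP4 = 0.34, C6 = 0.28),
                           "right hand" = c(C3 = 0.40, CP3 = 0.34, C5 = 0.28),
                           "legs"       = c(Cz = 0.28, FCz = 0.25, CPz = 0.25),
                           "tongue"     = c(C5 = 0.20, C6 = 0.20, FCz = 0.12)),
                         ramp_s = 0.25) {
  for (cls in names(erd)) {
    a <- erd[[cls]]
    if (any(a < 0 | a > 1)) stop("ERD attenuations must lie in [0, 1]")
    missing <- setdiff(names(a), channels)
    if (length(missing) > 0)
      stop("ERD names unknown channel(s): ", paste(missing, collapse = ", "))
  }
  if (!all(names(erd) %in% MI_CLASSES))
    stop("erd must be named by the four MI classes")
  structure(list(channels = channels, fs = fs, t_start = t_start,
                 t_end = t_end, imagery = imagery, mu_freq = mu_freq,
                 beta_freq = beta_freq, mu_amp = mu_amp,
                 beta_amp = beta_amp, noise_sd = noise_sd, erd = erd,
                 ramp_s = ramp_s),
            class = "eeg_sim_spec")
}

# 1/f-amplitude noise via spectral shaping of white Gaussian noise,
# standardized to unit variance
pink_noise <- function(n) {
  x <- rnorm(n)
  X <- fft(x)
  f <- c(1, seq_len(n - 1))
  f <- pmin(f, n - f + 1)          # two-sided frequency index, >= 1
  X <- X / sqrt(f)
  y <- Re(fft(X, inverse = TRUE)) / n
  (y - mean(y)) / sd(y)
}

erd_envelope <- function(t, imagery, ramp_s) {
  env <- numeric(length(t))
  inside <- t >= imagery[1] & t <= imagery[2]
  env[inside] <- 1
  if (ramp_s > 0) {
    up <- t >= imagery[1] & t < imagery[1] + ramp_s
    env[up] <- 0.5 * (1 - cos(pi * (t[up] - imagery[1]) / ramp_s))
    dn <- t > imagery[2] - ramp_s & t <= imagery[2]
    env[dn] <- pmin(env[dn],
                    0.5 * (1 - cos(pi * (imagery[2] - t[dn]) / ramp_s)))
  }
  env
}

#' Generate synthetic labelled motor-imagery epochs
#'
#' Each trial is pink noise plus mu and beta sinusoids (random phase per
#' trial and channel); on the channels listed in the trial's class ERD map
#' the rhythm amplitude is scaled by `1 - attenuation` during the imagery
#' interval (raised-cosine on/offset). Class labels are balanced and the
#' trial order is shuffled. Fully reproducible from `seed`.
#'
#' @param spec an [eeg_sim_spec()].
#' @param n_trials total number of trials (split evenly over the 4 classes).
#' @param seed RNG seed; `NULL` uses the current RNG state.
#' @return an `eeg_epochs` with `t_start = spec$t_start`.
#' @export
generate_mi_eeg <- function(spec, n_trials, seed = NULL) {
  stopifnot(inherits(spec, "eeg_sim_spec"))
  if (!is.null(seed)) set.seed(seed)
  n_samp <- as.integer(round((spec$t_end - spec$t_start) * spec$fs))
  t <- spec$t_start + (seq_len(n_samp) - 1L) / spec$fs
  n_ch <- length(spec$channels)
  labels <- sample(rep(0:3, length.out = n_trials))
  data <- array(0, dim = c(n_trials, n_ch, n_samp))
  env <- erd_envelope(t, spec$imagery, spec$ramp_s)
  for (tr in seq_len(n_trials)) {
    cls <- MI_CLASSES[labels[tr] + 1L]
    att <- spec$erd[[cls]]
    for (ch in seq_len(n_ch)) {
      a <- 0
      if (!is.null(att) && spec$channels[ch] %in% names(att))
        a <- att[[spec$channels[ch]]]
      gain <- 1 - a * env
      x <- spec$noise_sd * pink_noise(n_samp)
      x <- x + spec$mu_amp * gain *
        sin(2 * pi * spec$mu_freq * t + runif(1, 0, 2 * pi))
      x <- x + spec$beta_amp * gain *
        sin(2 * pi * spec$beta_freq * t + runif(1, 0, 2 * pi))
      data[tr, ch, ] <- x
    }
  }
  eeg_epochs(data, labels, spec$fs, spec$channels, t_start = spec$t_start)
}

#' Welch-style band power of one channel segment
#'
#' Mean one-sided periodogram power within a frequency band; used as an
#' independent oracle for the generator's ERD calibration.
#'
#' @param x numeric vector.
#' @param fs sampling rate (Hz).
#' @param band `c(lo, hi)` in Hz.
#' @param n_seg number of 50%-overlapping Hann segments.
#' @return mean band power.
#' @export
band_power <- function(x, fs, band, n_seg = 8) {
  n <- length(x)
  seg_len <- floor(2 * n / (n_seg + 1))
  hop <- floor(seg_len / 2)
  win <- 0.5 * (1 - cos(2 * pi * seq_len(seg_len) / (seg_len + 1)))
  starts <- seq(1, n - seg_len + 1, by = hop)
  f <- (seq_len(seg_len) - 1) * fs / seg_len
  sel <- f >= band[1] & f <= band[2]
  ps <- sapply(starts, function(s) {
    seg <- x[s:(s + seg_len - 1)] * win
    (Mod(fft(seg))^2 / sum(win^2))[sel]
  })
  mean(ps)
}
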