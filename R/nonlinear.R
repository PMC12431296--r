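#' Wavelet-packet decomposition configuration
#'
#' A 5-level db4 wavelet-packet decomposition splits the spectrum into
#' 32 equal leaves of width `fs / 64` Hz (3.906 Hz at 250 Hz). The default
#' keeps the six frequency-ordered leaves with indices 2-7, spanning about
#' 7.8-31.25 Hz, i.e. the mu/beta range the preprocessing band-pass keeps.
#'
#' @param wavelet mother wavelet; only `"db4"` is implemented.
#' @param levels decomposition depth.
#' @param leaves 0-based frequency-ordered leaf indices to keep.
#' @return a `wpd_config` list.
#' @export
wpd_config <- function(wavelet = "db4", levels = 5, leaves = 2:7) {
  if (!identical(wavelet, "db4"))
    stop("only the db4 wavelet is implemented")
  if (levels < 1) stop("levels must be >= 1")
  if (any(leaves < 0 | leaves >= 2^levels))
    stop("leaf indices must lie in [0, 2^levels)")
  structure(list(wavelet = wavelet, levels = as.integer(levels),
                 leaves = as.integer(leaves)), class = "wpd_config")
}

#' Wavelet-packet sub-band energies
#'
#' Decomposes each channel of a window to the configured depth and returns
#' the energy (sum of squared coefficients) of the selected leaves. Because
#' the periodized transform is orthogonal, the energies of all `2^levels`
#' leaves sum to the time-domain energy of the signal.
#'
#' @param window channels x samples matrix (or a numeric vector for a
#'   single channel).
#' @param cfg a [wpd_config()].
#' @param all_leaves if `TRUE`, return all `2^levels` leaf energies instead
#'   of the configured subset.
#' @return channels x n_leaves energy matrix (frequency-ordered columns).
#' @export
wpd_energy <- function(window, cfg = wpd_config(), all_leaves = FALSE) {
  if (is.vector(window)) window <- matrix(window, nrow = 1)
  if (ncol(window) < 2^cfg$levels)
    stop("window shorter than the decomposition support (2^levels samples)")
  idx <- if (all_leaves) seq_len(2^cfg$levels) else cfg$leaves + 1L
  out <- matrix(0, nrow(window), length(idx))
  for (ch in seq_len(nrow(window))) {
    e <- wpd_leaf_energies_cpp(window[ch, ], cfg$levels)
    out[ch, ] <- e[idx]
  }
  out
}

#' Sample entropy
#'
#' `-ln(A/B)` where `B` counts template pairs of length `m` within
#' Chebyshev tolerance `r` and `A` the pairs that still match when extended
#' to `m + 1` points (self-matches excluded). Low values indicate a regular
#' signal, high values a random one.
#'
#' @param x numeric vector, length at least `m + 2`.
#' @param m embedding dimension.
#' @param r tolerance radius; default `0.2 * sd(x)`.
#' @return scalar sample entropy. When no template pair matches at either
#'   length the value is undefined; a capped estimate
#'   `-ln(2 / ((N - m - 1) * (N - m)))` is returned with a warning.
#' @export
sample_entropy <- function(x, m = 2, r = 0.2 * sd(x)) {
  n <- length(x)
  if (n < m + 2) stop("series too short for embedding dimension m")
  if (!is.finite(r) || r <= 0) stop("tolerance r must be positive")
  cnt <- sampen_counts_cpp(as.numeric(x), as.integer(m), r)
  if (cnt$B == 0 || cnt$A == 0) {
    warning("no template matches; returning capped sample entropy")
    return(-log(2 / ((n - m - 1) * (n - m))))
  }
  -log(cnt$A / cnt$B)
}

#' Spectral entropy
#'
#' Shannon entropy (base 2, unnormalized) of the one-sided periodogram
#' after normalizing bin powers to sum to one. The DC bin is excluded so a
#' constant offset does not register as spectral structure.
#'
#' @param x numeric vector.
#' @param fs sampling rate (kept for interface symmetry; the entropy
#'   itself depends only on the power distribution over bins).
#' @return spectral entropy in bits.
#' @export
spectral_entropy <- function(x, fs = 250) {
  n <- length(x)
  pw <- Mod(fft(x))^2
  bins <- 2:(floor(n / 2) + 1L)         # exclude DC, keep up to Nyquist
  p <- pw[bins]
  tot <- sum(p)
  if (tot <= 0) stop("all-zero signal has no spectral distribution")
  p <- p / tot
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Higuchi fractal dimension
#'
#' Builds `k` subsampled curves for each step size `k = 1..k_max`, averages
#' their normalized lengths `L(k)`, and estimates the fractal dimension as
#' the slope of `log(L(k))` against `log(1/k)`. A straight line gives 1,
#' white noise about 2.
#'
#' @param x numeric vector longer than `k_max`.
#' @param k_max largest step size (>= 2).
#' @return scalar fractal dimension estimate.
#' @export
fractal_dimension <- function(x, k_max = 8) {
  if (k_max < 2) stop("k_max must be >= 2")
  if (length(x) <= k_max) stop("series must be longer than k_max")
  L <- higuchi_lengths_cpp(as.numeric(x), as.integer(k_max))
  if (any(L <= 0)) stop("constant signal: curve length is zero")
  k <- seq_len(k_max)
  unname(coef(lm(log(L) ~ log(1 / k)))[2])
}

#' Nonlinear feature configuration
#'
#' @param m sample-entropy embedding dimension.
#' @param r_factor sample-entropy tolerance as a fraction of the window's
#'   standard deviation.
#' @param k_max Higuchi step-size bound.
#' @return a `nonlinear_config` list.
#' @export
nonlinear_config <- function(m = 2, r_factor = 0.2, k_max = 8) {
  structure(list(m = as.integer(m), r_factor = r_factor,
                 k_max = as.integer(k_max)), class = "nonlinear_config")
}

#' Per-channel nonlinear features of one window
#'
#' @param window channels x samples matrix (band-filtered).
#' @param cfg a [nonlinear_config()].
#' @param fs sampling rate.
#' @return vector `[SampEn per channel | SpecEn per channel | FD per
#'   channel]` of length `3 * n_channels`.
#' @export
nonlinear_features <- function(window, cfg = nonlinear_config(), fs = 250) {
  if (is.vector(window)) window <- matrix(window, nrow = 1)
  nch <- nrow(window)
  sa <- sp <- fd <- numeric(nch)
  for (ch in seq_len(nch)) {
    x <- window[ch, ]
    sa[ch] <- sample_entropy(x, cfg$m, cfg$r_factor * sd(x))
    sp[ch] <- spectral_entropy(x, fs)
    fd[ch] <- fractal_dimension(x, cfg$k_max)
  }
  c(sa, sp, fd)
}
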