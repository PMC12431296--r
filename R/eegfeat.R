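#' Default motor-imagery filter bank
#'
#' Eleven 4 Hz-wide overlapping bands stepping by 2 Hz from 8-12 Hz up to
#' 28-32 Hz, covering the mu and beta rhythms.
#'
#' @param start first band lower edge (Hz).
#' @param width band width (Hz).
#' @param step spacing between band lower edges (Hz).
#' @param n_bands number of bands.
#' @return a `filter_bank`: list of `c(lo, hi)` pairs.
#' @export
filter_bank <- function(start = 8, width = 4, step = 2, n_bands = 11) {
  bands <- lapply(seq_len(n_bands) - 1L,
                  function(i) c(start + i * step, start + i * step + width))
  structure(bands, class = "filter_bank")
}

shrink_cov <- function(C, gamma) {
  if (gamma <= 0) return(C)
  m <- nrow(C)
  (1 - gamma) * C + gamma * (sum(diag(C)) / m) * diag(m)
}

#' Fit a two-class common spatial pattern filter
#'
#' Solves the generalized eigenproblem `C1 w = lambda (C1 + C2) w` by
#' whitening the composite covariance, yielding spatial filters that
#' maximize the variance ratio between the two classes. Columns of `W` are
#' sorted by descending eigenvalue and satisfy the whitening constraint
#' `t(W) %*% (C1 + C2) %*% W = I`.
#'
#' @param C1,C2 symmetric positive semi-definite class covariance matrices
#'   of equal size.
#' @param k number of filters to return (default: all).
#' @param shrinkage diagonal-loading coefficient in `[0, 1)` applied to each
#'   covariance before inversion (guards rank-deficient estimates).
#' @return channels x k matrix `W` with attribute `"eigenvalues"` (the
#'   generalized eigenvalues of `C1` against `C1 + C2`, descending).
#' @export
csp_fit <- function(C1, C2, k = NULL, shrinkage = 0.05) {
  if (!all(dim(C1) == dim(C2))) stop("C1 and C2 must have the same size")
  C1 <- shrink_cov((C1 + t(C1)) / 2, shrinkage)
  C2 <- shrink_cov((C2 + t(C2)) / 2, shrinkage)
  Sig <- C1 + C2
  es <- eigen(Sig, symmetric = TRUE)
  tol <- max(es$values) * 1e-12
  if (any(es$values < tol)) {
    # retry with stronger regularization before giving up
    Sig <- shrink_cov(Sig, 0.1)
    es <- eigen(Sig, symmetric = TRUE)
    if (any(es$values < max(es$values) * 1e-12))
      stop("composite covariance is singular even after regularization")
  }
  P <- diag(1 / sqrt(es$values)) %*% t(es$vectors)   # whitening: P Sig P' = I
  S <- P %*% C1 %*% t(P)
  ev <- eigen((S + t(S)) / 2, symmetric = TRUE)      # descending by default
  W <- t(P) %*% ev$vectors
  if (!is.null(k)) W <- W[, seq_len(k), drop = FALSE]
  attr(W, "eigenvalues") <- ev$values
  W
}

window_par <- function(win_s = 2.0, stride_s = 0.04, t_start_s = 1.0,
                       t_end_s = 4.0) {
  list(win_s = win_s, stride_s = stride_s, t_start_s = t_start_s,
       t_end_s = t_end_s)
}

# normalized spatial covariance of one window (channels x samples)
window_cov <- function(X) {
  C <- tcrossprod(X)
  C / sum(diag(C))
}

# Iterate band-filtered windows of trial-level epochs, calling fn(X, trial,
# label) for each window. Filtering happens at trial level so filtfilt
# transients stay outside the analysis span.
band_window_apply <- function(epochs, band, wp, fn) {
  filt <- butter_bandpass(band[1], band[2], 4, epochs$fs)
  nt <- n_trials(epochs)
  for (tr in seq_len(nt)) {
    xf <- apply_filtfilt(filt, epochs$data[tr, , , drop = TRUE])
    wins <- window_segment(xf, epochs$fs, wp$win_s, wp$stride_s,
                           wp$t_start_s, wp$t_end_s, epochs$t_start)
    for (w in seq_along(wins)) fn(wins[[w]], tr, epochs$labels[tr])
  }
  invisible(NULL)
}

#' Fit the filter-bank CSP model
#'
#' For every band of the filter bank, band-filters the trials, cuts
#' analysis windows, averages normalized per-window covariances within each
#' class, and fits four one-vs-rest CSP problems (class against the mean of
#' the remaining classes), keeping the top eigen-component of each. This
#' yields exactly 4 spatial filters per band and 44 features over the
#' 11-band default.
#'
#' @param epochs trial-level `eeg_epochs` (raw or broadband-filtered; each
#'   band is filtered from this input).
#' @param bank a [filter_bank()].
#' @param wp window parameters from [window_par()].
#' @param shrinkage covariance shrinkage passed to [csp_fit()].
#' @return a `fbcsp_model` with per-band filter matrices `W` (channels x 4);
#'   element `features` holds the training-window feature matrix so the
#'   fitting pass is not repeated.
#' @export
fbcsp_fit <- function(epochs, bank = filter_bank(), wp = window_par(),
                      shrinkage = 0.05) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  classes <- 0:3
  if (length(unique(epochs$labels)) < 2)
    stop("need at least two classes to fit CSP")
  n_ch <- dim(epochs$data)[2]
  Ws <- vector("list", length(bank))
  feat_blocks <- vector("list", length(bank))
  for (b in seq_along(bank)) {
    covsum <- lapply(classes, function(c) matrix(0, n_ch, n_ch))
    names(covsum) <- as.character(classes)
    cnt <- setNames(numeric(4), as.character(classes))
    covs_env <- environment()
    band_window_apply(epochs, bank[[b]], wp, function(X, tr, lab) {
      key <- as.character(lab)
      covs_env$covsum[[key]] <- covs_env$covsum[[key]] + window_cov(X)
      covs_env$cnt[key] <- covs_env$cnt[key] + 1
    })
    present <- names(cnt)[cnt > 0]
    cbar <- lapply(present, function(key) covsum[[key]] / cnt[key])
    names(cbar) <- present
    W <- matrix(0, n_ch, 4)
    for (ci in seq_along(classes)) {
      key <- as.character(classes[ci])
      if (!key %in% present) next
      rest <- present[present != key]
      C1 <- cbar[[key]]
      C2 <- Reduce(`+`, cbar[rest]) / length(rest)
      W[, ci] <- csp_fit(C1, C2, k = 1, shrinkage = shrinkage)
    }
    Ws[[b]] <- W
    feat_blocks[[b]] <- NULL
  }
  model <- structure(list(bank = bank, W = Ws, wp = wp,
                          shrinkage = shrinkage, n_channels = n_ch,
                          channel_names = epochs$channel_names),
                     class = "fbcsp_model")
  model$features <- fbcsp_features(epochs, bank, model)
  model
}

#' Filter-bank CSP log-variance features
#'
#' Projects each band-filtered analysis window through the fitted spatial
#' filters and takes, per band, the log ratio of each retained component's
#' variance to the summed variance of the retained components. Per-band the
#' four features therefore satisfy `sum(exp(f)) == 1`.
#'
#' @param epochs trial-level `eeg_epochs` on the channel set the model was
#'   fitted on.
#' @param bank filter bank (defaults to the model's own).
#' @param model a fitted `fbcsp_model`.
#' @return windows x 44 feature matrix (window order: trial-major); the
#'   origin trial of each row is in attribute `"trial_id"`.
#' @export
fbcsp_features <- function(epochs, bank = NULL, model) {
  stopifnot(inherits(model, "fbcsp_model"))
  if (is.null(bank)) bank <- model$bank
  if (dim(epochs$data)[2] != model$n_channels)
    stop("channel count differs from the fitted model")
  wp <- model$wp
  rows_env <- new.env()
  rows_env$out <- NULL
  rows_env$tid <- NULL
  for (b in seq_along(bank)) {
    W <- model$W[[b]]
    vals <- list()
    tid <- integer(0)
    i <- 0L
    band_window_apply(epochs, bank[[b]], wp, function(X, tr, lab) {
      Z <- crossprod(W, X)
      v <- apply(Z, 1L, var)
      if (any(v <= 0)) stop("zero-variance projected component")
      i <<- i + 1L
      vals[[i]] <<- log(v / sum(v))
      tid[i] <<- tr
    })
    block <- do.call(rbind, vals)
    if (is.null(rows_env$out)) {
      rows_env$out <- block
      rows_env$tid <- tid
    } else {
      rows_env$out <- cbind(rows_env$out, block)
    }
  }
  out <- rows_env$out
  attr(out, "trial_id") <- rows_env$tid
  out
}
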