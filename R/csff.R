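#' Configuration of the channel-selection / feature-fusion EEG classifier
#'
#' Bundles every tunable of the motor-imagery branch with the defaults used
#' throughout: 8-32 Hz order-4 Butterworth band-pass, -200..0 ms baseline,
#' 2 s windows with 0.04 s stride over the 1-4 s post-cue span (26 windows
#' per trial), 15 selected channels, 11-band filter bank, 5-level db4
#' wavelet packets, SampEn(m = 2, r = 0.2 sd), Higuchi k_max = 8, PCA at
#' 95% variance, RBF-SVR with cost 1 and epsilon 0.1.
#'
#' @param band broadband filter edges (Hz).
#' @param order Butterworth prototype order.
#' @param baseline baseline window (s relative to cue).
#' @param wp analysis-window parameters, see [window_par()].
#' @param selection a [selection_config()].
#' @param bank a [filter_bank()].
#' @param wpd a [wpd_config()].
#' @param nl a [nonlinear_config()].
#' @param pca_var cumulative variance retained by the feature PCA.
#' @param svr list of SVR hyperparameters.
#' @param shrinkage CSP covariance shrinkage.
#' @return a `csff_config` list.
#' @export
csff_config <- function(band = c(8, 32), order = 4, baseline = c(-0.2, 0),
                        wp = window_par(), selection = selection_config(),
                        bank = filter_bank(), wpd = wpd_config(),
                        nl = nonlinear_config(), pca_var = 0.95,
                        svr = list(cost = 1, epsilon = 0.1, gamma = NULL,
                                   kernel = "radial"),
                        shrinkage = 0.05) {
  structure(list(band = band, order = order, baseline = baseline, wp = wp,
                 selection = selection, bank = bank, wpd = wpd, nl = nl,
                 pca_var = pca_var, svr = svr, shrinkage = shrinkage),
            class = "csff_config")
}

crop_epochs <- function(epochs, t0, t1) {
  i0 <- round((t0 - epochs$t_start) * epochs$fs) + 1L
  i1 <- round((t1 - epochs$t_start) * epochs$fs)
  d <- dim(epochs$data)
  if (i0 < 1L || i1 > d[3]) stop("crop window outside epoch")
  epochs$data <- epochs$data[, , i0:i1, drop = FALSE]
  epochs$t_start <- t0
  epochs
}

preprocess_epochs <- function(epochs, config) {
  ep <- bandpass_filter(epochs, config$band[1], config$band[2], config$order)
  baseline_correct(ep, config$baseline[1], config$baseline[2])
}

# wavelet-packet + nonlinear features for every analysis window,
# trial-major order (matches fbcsp_features)
wpd_nl_features <- function(epochs, config) {
  wp <- config$wp
  rows <- list()
  tid <- integer(0)
  labs <- integer(0)
  k <- 0L
  for (tr in seq_len(n_trials(epochs))) {
    wins <- window_segment(epochs$data[tr, , , drop = TRUE], epochs$fs,
                           wp$win_s, wp$stride_s, wp$t_start_s, wp$t_end_s,
                           epochs$t_start)
    for (w in seq_along(wins)) {
      k <- k + 1L
      e <- wpd_energy(wins[[w]], config$wpd)
      rows[[k]] <- c(as.vector(t(e)),                      # ch1 leaves..chN
                     nonlinear_features(wins[[w]], config$nl, epochs$fs))
      tid[k] <- tr
      labs[k] <- epochs$labels[tr]
    }
  }
  out <- do.call(rbind, rows)
  nch <- dim(epochs$data)[2]
  list(wpd = out[, seq_len(nch * length(config$wpd$leaves)), drop = FALSE],
       nl = out[, -seq_len(nch * length(config$wpd$leaves)), drop = FALSE],
       trial_id = tid, labels = labs)
}

#' Fit the full motor-imagery EEG classifier
#'
#' End-to-end training: broadband filtering and baseline correction,
#' channel selection (fixed C3/Cz/C4 core plus scored candidates),
#' filter-bank CSP, wavelet-packet energies and nonlinear features per
#' analysis window, PCA + standardization, and one-vs-rest SVR on the
#' window-level features.
#'
#' @param epochs trial-level `eeg_epochs` covering at least the baseline
#'   and the 1-4 s post-cue analysis span.
#' @param config a [csff_config()].
#' @param channels optional fixed channel set (skips selection).
#' @return a `csff_model`.
#' @export
csff_fit <- function(epochs, config = csff_config(), channels = NULL) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  ep <- preprocess_epochs(epochs, config)
  selection_table <- NULL
  if (is.null(channels)) {
    scoring <- crop_epochs(ep, config$wp$t_start_s, config$wp$t_end_s)
    channels <- select_mi_channels(scoring, config$selection)
    selection_table <- attr(channels, "table")
  }
  ep_sel <- select_channels(ep, channels)
  fb <- fbcsp_fit(ep_sel, config$bank, config$wp, config$shrinkage)
  f_fbcsp <- fb$features
  fb$features <- NULL
  other <- wpd_nl_features(ep_sel, config)
  asm <- assemble_features(
    list(fbcsp = f_fbcsp, wpd = other$wpd, nl = other$nl),
    var_explained = config$pca_var)
  svr <- do.call(ovr_svr_fit, c(list(x = asm$features, y = other$labels),
                                config$svr))
  structure(list(config = config, channels = as.character(channels),
                 selection_table = selection_table, fbcsp = fb,
                 state = asm$state, block_widths = asm$block_widths,
                 svr = svr),
            class = "csff_model")
}

#' @export
print.csff_model <- function(x, ...) {
  cat(sprintf("<csff_model> %d channels (%s...), %d fused dims -> %d PCs\n",
              length(x$channels), paste(head(x$channels, 5), collapse = ","),
              sum(x$block_widths), x$state$k))
  invisible(x)
}

#' Window features for a trained CSFF model
#'
#' @param model a `csff_model`.
#' @param epochs trial-level `eeg_epochs` on the full channel montage.
#' @return list with the standardized feature matrix, window labels and
#'   trial ids.
#' @export
csff_features <- function(model, epochs) {
  config <- model$config
  ep_sel <- select_channels(preprocess_epochs(epochs, config),
                            model$channels)
  f_fbcsp <- fbcsp_features(ep_sel, model = model$fbcsp)
  other <- wpd_nl_features(ep_sel, config)
  asm <- assemble_features(
    list(fbcsp = f_fbcsp, wpd = other$wpd, nl = other$nl),
    state = model$state)
  list(features = asm$features, labels = other$labels,
       trial_id = other$trial_id)
}

#' Predict motor-imagery classes with a trained CSFF model
#'
#' Runs per-window prediction and aggregates windows into per-trial
#' decisions by majority vote (ties resolved by mean window probability).
#'
#' @param model a fitted `csff_model`.
#' @param epochs trial-level `eeg_epochs` to classify.
#' @return list with `class` (per trial), `p_mi` (trial x 4 probability
#'   matrix for fusion), `window_class`, `window_p`, `trial_id` and
#'   `labels` (true labels carried through for convenience).
#' @export
csff_predict <- function(model, epochs) {
  stopifnot(inherits(model, "csff_model"))
  ft <- csff_features(model, epochs)
  wp <- ovr_svr_predict(model$svr, ft$features)
  agg <- predict_trial(wp, ft$trial_id)
  list(class = agg$class, p_mi = agg$p_mi,
       window_class = wp$class, window_p = wp$p_mi,
       trial_id = ft$trial_id,
       labels = epochs$labels[agg$trials])
}
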