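#' Channel-selection configuration
#'
#' Motor imagery depends on primary motor cortex, which maps onto scalp
#' electrodes C3 (right-hand area), Cz (midline/leg area) and C4 (left-hand
#' area); these core channels are always retained for spatial-filter
#' stability. The remaining candidates are scored and the best
#' `k_total - 3` are added.
#'
#' @param k_total total number of channels to select, core included
#'   (default 15).
#' @param alpha weight of the variance score in the fused score, in `[0,1]`;
#'   0.5 weighs both criteria equally.
#' @param epsilon smoothing constant guarding the variance-ratio denominator.
#' @param core fixed core channel names.
#' @param pooled_class_variance if `TRUE`, the within-class variance is
#'   computed on the pooled samples of each class instead of the default
#'   mean of per-trial variances.
#' @return a `selection_config` list.
#' @export
selection_config <- function(k_total = 15, alpha = 0.5, epsilon = 1e-10,
                             core = c("C3", "Cz", "C4"),
                             pooled_class_variance = FALSE) {
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]")
  if (epsilon <= 0) stop("epsilon must be > 0")
  if (k_total < length(core)) stop("k_total must be >= number of core channels")
  structure(list(k_total = as.integer(k_total), alpha = alpha,
                 epsilon = epsilon, core = core,
                 pooled_class_variance = pooled_class_variance),
            class = "selection_config")
}

channel_index <- function(epochs, channel) {
  idx <- if (is.character(channel)) match(channel, epochs$channel_names)
         else as.integer(channel)
  if (is.na(idx) || idx < 1L || idx > length(epochs$channel_names))
    stop("channel not found: ", channel)
  idx
}

#' Discriminative variance score of one channel
#'
#' Ratio of class-conditional signal variance to pooled variance, averaged
#' over the N = 4 classes: channels whose fluctuation depends strongly on
#' the imagined movement score above 1, non-selective channels near 1, and
#' silent channels near 0.
#'
#' @param epochs band-filtered `eeg_epochs` with at least 2 trials per class.
#' @param channel channel name or index.
#' @param epsilon denominator smoothing.
#' @param pooled_class_variance see [selection_config()].
#' @return scalar score `S_var`.
#' @export
discriminative_variance_score <- function(epochs, channel, epsilon = 1e-10,
                                          pooled_class_variance = FALSE) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  idx <- channel_index(epochs, channel)
  x <- epochs$data[, idx, , drop = TRUE]    # trials x samples
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  classes <- sort(unique(epochs$labels))
  cnt <- tabulate(epochs$labels + 1L, 4L)
  if (any(cnt < 2L))
    stop("need at least 2 trials in every class")
  pooled <- var(as.vector(x))
  s <- 0
  for (j in classes) {
    xj <- x[epochs$labels == j, , drop = FALSE]
    vj <- if (pooled_class_variance) var(as.vector(xj))
          else mean(apply(xj, 1L, var))
    s <- s + vj / (pooled + epsilon)
  }
  s / length(classes)
}

#' Per-trial mean-square power of one channel
#'
#' @param epochs an `eeg_epochs`.
#' @param channel channel name or index.
#' @return numeric vector, one power value per trial.
#' @export
trial_power <- function(epochs, channel) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  idx <- channel_index(epochs, channel)
  x <- epochs$data[, idx, , drop = TRUE]
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  rowMeans(x^2)
}

#' ANOVA band-power significance score of one channel
#'
#' Computes per-trial mean-square power on the (already band-filtered)
#' signal, groups powers by imagery class, runs a classical one-way ANOVA
#' F-test, and returns `-log10(p)`. Channels whose mu/beta power is
#' modulated differently by the four tasks (event-related
#' desynchronization) get large scores.
#'
#' @inheritParams discriminative_variance_score
#' @return scalar score `S_anova` (0 when the powers carry no group
#'   structure; p-values are floored at 1e-300 before the logarithm).
#' @export
anova_power_score <- function(epochs, channel) {
  p <- trial_power(epochs, channel)
  g <- factor(epochs$labels, levels = 0:3)
  if (any(tabulate(g) > 0 & tabulate(g) < 2))
    stop("need at least 2 trials in every class")
  if (max(p) - min(p) <= .Machine$double.eps * max(abs(p), 1)) {
    warning("all trial powers identical; ANOVA F undefined, score set to 0")
    return(0)
  }
  pv <- tryCatch(
    oneway.test(p ~ g, var.equal = TRUE)$p.value,
    error = function(e) NA_real_)
  if (is.na(pv) || is.nan(pv)) {
    warning("ANOVA p-value undefined; score set to 0")
    return(0)
  }
  -log10(max(pv, 1e-300))
}

#' Score all candidate channels
#'
#' Applies both scoring criteria to every non-core channel of a
#' band-filtered epoch set.
#'
#' @param epochs band-filtered `eeg_epochs`.
#' @param config a [selection_config()].
#' @return a `channel_score_table` data.frame with columns `channel`,
#'   `is_core`, `s_var`, `s_anova` (raw scores; core rows carry raw scores
#'   too but never enter normalization).
#' @export
channel_scores <- function(epochs, config = selection_config()) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  missing_core <- setdiff(config$core, epochs$channel_names)
  if (length(missing_core) > 0)
    stop("core channels absent from epochs: ",
         paste(missing_core, collapse = ", "))
  tab <- data.frame(
    channel = epochs$channel_names,
    is_core = epochs$channel_names %in% config$core,
    s_var = vapply(epochs$channel_names, function(ch)
      discriminative_variance_score(epochs, ch, config$epsilon,
                                    config$pooled_class_variance), 0),
    s_anova = vapply(epochs$channel_names, function(ch)
      anova_power_score(epochs, ch), 0),
    stringsAsFactors = FALSE, row.names = NULL)
  class(tab) <- c("channel_score_table", "data.frame")
  tab
}

minmax_norm <- function(x) {
  rng <- max(x) - min(x)
  if (rng <= 0) {
    # degenerate: all candidates share one value; normalized score carries
    # no information, set to 0 so selection falls back to the other score
    return(rep(0, length(x)))
  }
  (x - min(x)) / rng
}

#' Fuse channel scores and select the final channel set
#'
#' Min-max normalizes both scores over the candidate channels (core
#' channels are excluded from the normalization statistics), fuses them as
#' `alpha * s_var_norm + (1 - alpha) * s_anova_norm`, and selects the top
#' `k_total - |core|` candidates. Ties are broken by ascending original
#' channel index (stable rule).
#'
#' @param table a `channel_score_table` from [channel_scores()].
#' @param config a [selection_config()].
#' @return character vector of selected channel names, core channels first,
#'   then candidates in descending fused score. The augmented score table
#'   (columns `s_var_norm`, `s_anova_norm`, `s_fused`, `rank`, `selected`)
#'   is attached as attribute `"table"`.
#' @export
fuse_and_select <- function(table, config = selection_config()) {
  stopifnot(inherits(table, "data.frame"))
  cand <- which(!table$is_core)
  if (length(cand) < config$k_total - sum(table$is_core))
    stop("not enough candidate channels for k_total")
  table$s_var_norm <- NA_real_
  table$s_anova_norm <- NA_real_
  table$s_fused <- NA_real_
  table$s_var_norm[cand] <- minmax_norm(table$s_var[cand])
  table$s_anova_norm[cand] <- minmax_norm(table$s_anova[cand])
  table$s_fused[cand] <- config$alpha * table$s_var_norm[cand] +
    (1 - config$alpha) * table$s_anova_norm[cand]
  ord <- cand[order(-table$s_fused[cand], cand)]
  n_pick <- config$k_total - sum(table$is_core)
  picked <- ord[seq_len(n_pick)]
  table$rank <- NA_integer_
  table$rank[ord] <- seq_along(ord)
  table$selected <- table$is_core
  table$selected[picked] <- TRUE
  sel <- c(table$channel[table$is_core], table$channel[picked])
  attr(sel, "table") <- table
  sel
}

#' One-call channel selection
#'
#' Convenience wrapper: scores all candidates of a band-filtered epoch set
#' and returns the fused selection.
#'
#' @inheritParams channel_scores
#' @return as [fuse_and_select()].
#' @export
select_mi_channels <- function(epochs, config = selection_config()) {
  fuse_and_select(channel_scores(epochs, config), config)
}

#' Write a channel score table to CSV
#'
#' @param selection result of [fuse_and_select()] or [select_mi_channels()].
#' @param path output CSV path.
#' @export
write_score_table <- function(selection, path) {
  tab <- attr(selection, "table")
  if (is.null(tab)) stop("selection carries no score table")
  write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
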