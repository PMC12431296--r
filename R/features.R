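#' Fit the PCA + standardization state on a training feature matrix
#'
#' Principal components are fitted on the concatenated feature blocks,
#' sorted by explained variance, and truncated at the smallest count
#' explaining at least `var_explained` of the total variance; the retained
#' scores are then z-scored. The fitted state (rotation, centering, score
#' means/sds) is reused verbatim at transform time.
#'
#' @param x training feature matrix (rows = windows/trials).
#' @param var_explained cumulative explained-variance target in (0, 1], or
#'   `NULL` with `n_components` given explicitly.
#' @param n_components fixed number of components (overrides
#'   `var_explained`); clipped to the available rank with a warning.
#' @return a `feature_state` object.
#' @export
fit_feature_state <- function(x, var_explained = 0.95, n_components = NULL) {
  x <- as.matrix(x)
  pca <- prcomp(x, center = TRUE, scale. = FALSE)
  ev <- pca$sdev^2
  evr <- ev / sum(ev)
  if (!is.null(n_components)) {
    if (n_components > ncol(pca$rotation)) {
      warning(sprintf("n_components clipped from %d to available rank %d",
                      n_components, ncol(pca$rotation)))
      n_components <- ncol(pca$rotation)
    }
    k <- n_components
  } else {
    k <- which(cumsum(evr) >= var_explained)[1]
    if (is.na(k)) k <- length(evr)
  }
  scores <- pca$x[, seq_len(k), drop = FALSE]
  mu <- colMeans(scores)
  sdev <- apply(scores, 2L, sd)
  sdev[sdev < 1e-12] <- 1
  structure(list(rotation = pca$rotation[, seq_len(k), drop = FALSE],
                 center = pca$center, score_mean = mu, score_sd = sdev,
                 k = k, explained = cumsum(evr)[k], evr = evr[seq_len(k)]),
            class = "feature_state")
}

#' Apply a fitted feature state
#'
#' @param state a `feature_state` from [fit_feature_state()].
#' @param x feature matrix with the same columns as the training matrix.
#' @return rows x k matrix of standardized principal-component scores.
#' @export
apply_feature_state <- function(state, x) {
  if (!inherits(state, "feature_state"))
    stop("state is not a fitted feature_state")
  x <- as.matrix(x)
  if (ncol(x) != length(state$center))
    stop(sprintf("feature dimension mismatch: got %d, fitted on %d",
                 ncol(x), length(state$center)))
  scores <- sweep(x, 2L, state$center) %*% state$rotation
  sweep(sweep(scores, 2L, state$score_mean), 2L, state$score_sd, "/")
}

#' Concatenate feature blocks and compress them
#'
#' Binds the FBCSP, wavelet-packet and nonlinear blocks column-wise
#' (44 + 90 + 45 = 179 columns under the 15-channel defaults), records the
#' block boundaries, and either fits a fresh PCA/standardization state or
#' applies a previously fitted one.
#'
#' @param blocks named list of numeric matrices with equal row counts.
#' @param state `NULL` to fit a new state, or a fitted `feature_state`.
#' @param var_explained passed to [fit_feature_state()] when fitting.
#' @return list with `features` (transformed matrix), `state`, and
#'   `block_widths`.
#' @export
assemble_features <- function(blocks, state = NULL, var_explained = 0.95) {
  if (!is.list(blocks) || length(blocks) == 0)
    stop("blocks must be a non-empty list of matrices")
  blocks <- lapply(blocks, as.matrix)
  nr <- vapply(blocks, nrow, 0L)
  if (length(unique(nr)) != 1)
    stop("all feature blocks must have the same number of rows")
  x <- do.call(cbind, blocks)
  if (is.null(state)) state <- fit_feature_state(x, var_explained)
  list(features = apply_feature_state(state, x), state = state,
       block_widths = vapply(blocks, ncol, 0L))
}
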