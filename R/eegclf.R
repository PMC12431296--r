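softmax <- function(v) {
  e <- exp(v - max(v))
  e / sum(e)
}

#' Train the one-vs-rest SVR motor-imagery classifier
#'
#' Trains one epsilon-SVR per imagery class on the fused feature matrix,
#' with regression target 1 for windows of that class and 0 otherwise. At
#' prediction time the class whose regressor output is nearest 1 wins.
#'
#' @param x feature matrix (rows = analysis windows).
#' @param y integer labels in 0..3, one per row.
#' @param cost,epsilon,gamma SVR hyperparameters (`gamma = NULL` uses the
#'   `1/ncol(x)` kernel default).
#' @param kernel kernel name passed to [e1071::svm()].
#' @return an `ovr_svr_model` with four fitted regressors.
#' @export
ovr_svr_fit <- function(x, y, cost = 1, epsilon = 0.1, gamma = NULL,
                        kernel = "radial") {
  x <- as.matrix(x)
  y <- as.integer(y)
  if (length(y) != nrow(x)) stop("one label per row required")
  if (length(unique(y)) < 2)
    stop("need at least two classes to train a classifier")
  if (!all(y %in% 0:3)) stop("labels must be in 0..3")
  models <- vector("list", 4)
  for (c in 0:3) {
    target <- as.numeric(y == c)
    args <- list(x = x, y = target, type = "eps-regression",
                 kernel = kernel, cost = cost, epsilon = epsilon,
                 scale = FALSE)
    if (!is.null(gamma)) args$gamma <- gamma
    models[[c + 1]] <- do.call(e1071::svm, args)
  }
  structure(list(models = models, n_features = ncol(x)),
            class = "ovr_svr_model")
}

#' Per-window prediction with class probabilities
#'
#' Evaluates the four regressors on each row; the predicted class is the
#' one whose output is closest to 1 (ties to the lowest class index), and
#' the probability vector `P_MI` is the softmax of the raw outputs, exposed
#' for decision-level fusion.
#'
#' @param model a fitted `ovr_svr_model`.
#' @param x feature matrix in the model's fitted feature space.
#' @return list with `class` (integer vector), `p_mi` (rows x 4 matrix,
#'   rows sum to 1) and `raw` (regressor outputs).
#' @export
ovr_svr_predict <- function(model, x) {
  stopifnot(inherits(model, "ovr_svr_model"))
  x <- as.matrix(x)
  if (ncol(x) != model$n_features)
    stop(sprintf("feature dimension mismatch: got %d, fitted on %d",
                 ncol(x), model$n_features))
  raw <- vapply(model$models, function(m) as.numeric(predict(m, x)),
                numeric(nrow(x)))
  raw <- matrix(raw, nrow = nrow(x))
  cls <- apply(raw, 1L, function(v) which.min(abs(1 - v)) - 1L)
  p <- t(apply(raw, 1L, softmax))
  list(class = as.integer(cls), p_mi = p, raw = raw)
}

#' Aggregate window predictions into a per-trial decision
#'
#' Majority vote over the windows of each trial; ties are resolved by the
#' argmax of the window-averaged probability vector.
#'
#' @param pred result of [ovr_svr_predict()] on window features.
#' @param trial_id integer vector assigning each window row to a trial.
#' @return list with `class` (one per trial), `p_mi` (trial-level mean
#'   probabilities, renormalized) and `trials` (the trial ids, in the order
#'   classes are reported).
#' @export
predict_trial <- function(pred, trial_id) {
  if (length(trial_id) != length(pred$class))
    stop("trial_id must match the number of window predictions")
  trials <- unique(trial_id)
  cls <- integer(length(trials))
  pmat <- matrix(0, length(trials), 4)
  for (i in seq_along(trials)) {
    sel <- trial_id == trials[i]
    votes <- tabulate(pred$class[sel] + 1L, 4L)
    pbar <- colMeans(pred$p_mi[sel, , drop = FALSE])
    pbar <- pbar / sum(pbar)
    top <- which(votes == max(votes))
    cls[i] <- if (length(top) == 1L) top - 1L
              else (top[which.max(pbar[top])] - 1L)
    pmat[i, ] <- pbar
  }
  list(class = cls, p_mi = pmat, trials = trials)
}
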