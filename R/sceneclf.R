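as_scene_factor <- function(labels) {
  if (is.numeric(labels)) labels <- SCENES[labels + 1L]
  f <- factor(as.character(labels), levels = SCENES)
  if (anyNA(f)) stop("unknown scene label(s)")
  f
}

#' Stratified train/test split
#'
#' @param labels class labels.
#' @param ratio training fraction (default 0.7).
#' @param seed RNG seed for the split.
#' @return list with integer vectors `train` and `test`.
#' @export
stratified_split <- function(labels, ratio = 0.7, seed = 1) {
  set.seed(seed)
  train <- integer(0)
  for (lv in unique(labels)) {
    idx <- which(labels == lv)
    n_tr <- max(1L, round(ratio * length(idx)))
    train <- c(train, sample(idx, n_tr))
  }
  train <- sort(train)
  list(train = train, test = setdiff(seq_along(labels), train))
}

macro_f1 <- function(truth, pred) {
  lv <- unique(c(as.character(truth), as.character(pred)))
  f1 <- vapply(lv, function(l) {
    tp <- sum(truth == l & pred == l)
    fp <- sum(truth != l & pred == l)
    fn <- sum(truth == l & pred != l)
    if (tp == 0) return(0)
    prec <- tp / (tp + fp)
    rec <- tp / (tp + fn)
    2 * prec * rec / (prec + rec)
  }, 0)
  mean(f1)
}

#' Fit the scene classifier
#'
#' Compresses the structured scene features with PCA (50 components by
#' default) and fits a 100-tree probability random forest. The maximum
#' tree depth is chosen by stratified k-fold cross-validation over a small
#' grid (8, 12, 16, unlimited).
#'
#' @param features n_images x d feature matrix from [scene_featurize()].
#' @param labels scene labels (names from `SCENES`, or 0-based ids).
#' @param pca_dim PCA target dimension; clipped to the available rank with
#'   a warning; `NULL` skips PCA.
#' @param n_trees number of forest trees.
#' @param cv_folds folds for the depth search.
#' @param depth_grid candidate maximum depths (0 = unlimited).
#' @param seed RNG seed for forest and folds.
#' @return a `scene_model`.
#' @export
fit_scene <- function(features, labels, pca_dim = 50, n_trees = 100,
                      cv_folds = 10, depth_grid = c(8, 12, 16, 0),
                      seed = 1) {
  features <- as.matrix(features)
  y <- as_scene_factor(labels)
  tab <- table(droplevels(y))
  if (length(tab) < 2) stop("need samples from at least two scenes")
  if (any(tab < 2)) stop("need at least 2 samples per scene")
  state <- NULL
  x <- features
  attr(x, "layout") <- NULL
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  if (!is.null(pca_dim)) {
    state <- fit_feature_state(features, n_components = pca_dim)
    x <- apply_feature_state(state, features)
  }
  # stratified folds for the depth search
  set.seed(seed)
  fold <- integer(nrow(x))
  for (lv in levels(droplevels(y))) {
    idx <- sample(which(y == lv))
    fold[idx] <- rep_len(seq_len(cv_folds), length(idx))
  }
  cv_acc <- vapply(depth_grid, function(d) {
    accs <- vapply(seq_len(cv_folds), function(f) {
      tr <- fold != f
      if (length(unique(y[tr])) < 2 || sum(!tr) == 0) return(NA_real_)
      rf <- ranger::ranger(x = x[tr, , drop = FALSE], y = droplevels(y[tr]),
                           num.trees = n_trees, max.depth = d,
                           probability = TRUE, seed = seed,
                           num.threads = 1)
      pr <- predict(rf, x[!tr, , drop = FALSE], num.threads = 1)$predictions
      mean(colnames(pr)[max.col(pr, "first")] == as.character(y[!tr]))
    }, 0)
    mean(accs, na.rm = TRUE)
  }, 0)
  depth <- depth_grid[which.max(cv_acc)]
  forest <- ranger::ranger(x = x, y = droplevels(y), num.trees = n_trees,
                           max.depth = depth, probability = TRUE,
                           seed = seed, num.threads = 1)
  structure(list(state = state, forest = forest, depth = depth,
                 cv = data.frame(max_depth = depth_grid, cv_accuracy = cv_acc),
                 levels = levels(droplevels(y)), n_features = ncol(features)),
            class = "scene_model")
}

#' @export
print.scene_model <- function(x, ...) {
  cat(sprintf("<scene_model> %d-tree forest, max depth %s, %s\n",
              x$forest$num.trees,
              if (x$depth == 0) "unlimited" else x$depth,
              if (is.null(x$state)) "no PCA"
              else sprintf("PCA to %d dims (%.1f%% variance)",
                           x$state$k, 100 * x$state$explained)))
  invisible(x)
}

#' Predict scenes with class probabilities
#'
#' @param model a fitted `scene_model`.
#' @param features feature matrix with the columns the model was fitted on.
#' @return list with `scene` (0-based id into `SCENES`), `scene_name`, and
#'   `p_scene` (rows x 3 matrix of tree-vote fractions, rows sum to 1).
#' @export
predict_scene <- function(model, features) {
  if (!inherits(model, "scene_model")) stop("model is not a fitted scene_model")
  features <- as.matrix(features)
  if (ncol(features) != model$n_features)
    stop(sprintf("feature dimension mismatch: got %d, fitted on %d",
                 ncol(features), model$n_features))
  x <- if (is.null(model$state)) features
       else apply_feature_state(model$state, features)
  attr(x, "layout") <- NULL
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  pr <- predict(model$forest, x, num.threads = 1)$predictions
  p <- matrix(0, nrow(x), length(SCENES), dimnames = list(NULL, SCENES))
  p[, colnames(pr)] <- pr
  cls <- max.col(p, "first") - 1L
  list(scene = cls, scene_name = SCENES[cls + 1L], p_scene = p)
}

#' Feature-combination ablation harness
#'
#' Evaluates the scene classifier on nested feature subsets of the full
#' structured vector: presence + count (160 dims at C = 80), plus mean
#' confidence (240), plus the grid map compressed by PCA (50). Mirrors the
#' layout recorded in the feature matrix's `"layout"` attribute.
#'
#' @param features full scene feature matrix from [scene_featurize()].
#' @param labels scene labels.
#' @param ratio train fraction of the stratified split.
#' @param seed RNG seed (split, forest).
#' @param pca_dim PCA dimension used for the full combination only.
#' @return data.frame with columns `combo`, `dim`, `accuracy`, `f1`.
#' @export
ablation_harness <- function(features, labels, ratio = 0.7, seed = 1,
                             pca_dim = 50) {
  features <- as.matrix(features)
  layout <- attr(features, "layout")
  if (is.null(layout))
    stop("features must carry a 'layout' attribute (see scene_featurize)")
  y <- as_scene_factor(labels)
  sp <- stratified_split(y, ratio, seed)
  bounds <- cumsum(layout)
  combos <- list(
    "presence+count" = list(cols = seq_len(bounds[["cnt"]]), pca = NULL),
    "presence+count+confidence" = list(cols = seq_len(bounds[["conf"]]),
                                       pca = NULL),
    "presence+count+confidence+grid(PCA)" = list(
      cols = seq_len(bounds[["grid"]]), pca = pca_dim))
  out <- lapply(names(combos), function(nm) {
    cc <- combos[[nm]]
    if (length(cc$cols) == 0) stop("empty feature subset")
    xtr <- features[sp$train, cc$cols, drop = FALSE]
    xte <- features[sp$test, cc$cols, drop = FALSE]
    m <- fit_scene(xtr, y[sp$train], pca_dim = cc$pca, seed = seed)
    pred <- predict_scene(m, xte)
    dim_used <- if (is.null(cc$pca)) length(cc$cols) else m$state$k
    data.frame(combo = nm, dim = dim_used,
               accuracy = mean(pred$scene_name == as.character(y[sp$test])),
               f1 = macro_f1(as.character(y[sp$test]), pred$scene_name))
  })
  do.call(rbind, out)
}
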