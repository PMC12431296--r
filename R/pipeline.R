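mi_trial_accuracy <- function(pred, truth) mean(pred$class == truth)

#' Run the full multimodal pipeline end to end
#'
#' Trains the motor-imagery classifier and the scene recognizer on their
#' (synthetic by default) training splits, predicts the held-out test
#' splits, pairs EEG test trials with scene test images, fuses the two
#' posteriors per pair, and evaluates the resulting 12-way task decisions.
#' All randomness (generation, splits, pairing, forest) derives from
#' `config$seed`.
#'
#' @param config a [pipeline_config()].
#' @param eeg trial-level `eeg_epochs`, `NULL` to generate synthetic data,
#'   or `FALSE` to disable the EEG branch (scene-only marginal decisions,
#'   with a warning).
#' @param scene_data list with `detections` and `labels` (see
#'   [generate_scene_dataset()]), `NULL` for synthetic, or `FALSE` to
#'   disable the scene branch.
#' @param map a [task_map()].
#' @return a `pipeline_result` list: per-branch models and accuracies,
#'   the fused `decisions`, the per-task `report` (accuracy in percent),
#'   and bookkeeping (`seed`, `config_hash`).
#' @export
run_pipeline <- function(config = pipeline_config(), eeg = NULL,
                         scene_data = NULL,
                         map = task_map(config$task_map_path)) {
  seed <- config$seed
  use_eeg <- !isFALSE(eeg)
  use_scene <- !isFALSE(scene_data)
  if (!use_eeg && !use_scene)
    stop("at least one modality is required")

  mi_res <- NULL
  if (use_eeg) {
    if (is.null(eeg))
      eeg <- generate_mi_eeg(eeg_sim_spec(), config$eeg$n_trials, seed = seed)
    sp <- stratified_split(eeg$labels, 0.7, seed)
    train <- eeg; train$data <- eeg$data[sp$train, , , drop = FALSE]
    train$labels <- eeg$labels[sp$train]
    test <- eeg; test$data <- eeg$data[sp$test, , , drop = FALSE]
    test$labels <- eeg$labels[sp$test]
    model <- csff_fit(train, csff_config_from(config))
    pred <- csff_predict(model, test)
    mi_res <- list(model = model, pred = pred, truth = test$labels,
                   accuracy = mi_trial_accuracy(pred, test$labels),
                   window_accuracy = mean(pred$window_class ==
                                            test$labels[pred$trial_id]))
  } else {
    warning("EEG branch disabled; task decisions use a uniform MI posterior")
  }

  scene_res <- NULL
  if (use_scene) {
    if (is.null(scene_data))
      scene_data <- generate_scene_dataset(
        scene_sim_spec(), config$scene$n_per_scene, seed = seed + 1)
    feats <- scene_featurize(scene_data$detections,
                             n_grid = config$scene$n_grid,
                             min_score = config$scene$min_score)
    sp <- stratified_split(scene_data$labels, 0.7, seed + 1)
    model <- fit_scene(feats[sp$train, , drop = FALSE],
                       scene_data$labels[sp$train],
                       pca_dim = config$scene$pca_dim,
                       n_trees = config$scene$n_trees, seed = seed + 1)
    pred <- predict_scene(model, feats[sp$test, , drop = FALSE])
    truth <- scene_data$labels[sp$test]
    scene_res <- list(model = model, pred = pred, truth = truth,
                      accuracy = mean(pred$scene_name == truth))
  } else {
    warning("scene branch disabled; task decisions use a uniform scene posterior")
  }

  # pair EEG test trials with scene test images and fuse
  n_mi <- if (use_eeg) length(mi_res$truth) else 0L
  n_sc <- if (use_scene) length(scene_res$truth) else 0L
  n_pairs <- max(n_mi, n_sc)
  set.seed(seed + 2)
  mi_idx <- if (use_eeg) sample(n_mi, n_pairs, replace = TRUE) else NULL
  sc_idx <- if (use_scene) sample(n_sc, n_pairs, replace = TRUE) else NULL
  decisions <- vector("list", n_pairs)
  pred_task <- truth_task <- character(n_pairs)
  for (k in seq_len(n_pairs)) {
    p_mi <- if (use_eeg) mi_res$pred$p_mi[mi_idx[k], ] else rep(0.25, 4)
    p_sc <- if (use_scene) scene_res$pred$p_scene[sc_idx[k], ] else rep(1/3, 3)
    decisions[[k]] <- fuse(p_mi, p_sc, map, tau = config$fusion$tau)
    pred_task[k] <- decisions[[k]]$task
    mi_true <- if (use_eeg) mi_res$truth[mi_idx[k]] else decisions[[k]]$mi
    sc_true <- if (use_scene) match(scene_res$truth[sc_idx[k]], map$scenes)
               else decisions[[k]]$scene + 1L
    truth_task[k] <- map$names[mi_true + 1L, sc_true]
  }
  report <- evaluate_tasks(pred_task, truth_task, map)
  tf <- tempfile(fileext = ".json")
  write_config(config, tf)
  structure(list(mi = mi_res, scene = scene_res, decisions = decisions,
                 predicted_tasks = pred_task, true_tasks = truth_task,
                 report = report,
                 task_accuracy = mean(pred_task == truth_task),
                 seed = seed,
                 config_hash = unname(tools::md5sum(tf))),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  if (!is.null(x$mi))
    cat(sprintf("  MI accuracy (trial): %.1f%%  (window: %.1f%%)\n",
                100 * x$mi$accuracy, 100 * x$mi$window_accuracy))
  if (!is.null(x$scene))
    cat(sprintf("  Scene accuracy: %.1f%%\n", 100 * x$scene$accuracy))
  cat(sprintf("  Task accuracy over %d fused decisions: %.1f%%\n",
              length(x$decisions), 100 * x$task_accuracy))
  cat(sprintf("  seed %s, config %s\n", x$seed, x$config_hash))
  invisible(x)
}
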