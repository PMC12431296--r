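coco_id <- function(name) {
  i <- match(name, COCO_CATEGORIES)
  if (anyNA(i)) stop("unknown COCO category: ",
                     paste(name[is.na(i)], collapse = ", "))
  i - 1L
}

#' Simulation spec for scene-conditional object detections
#'
#' Emulates a detector's output on indoor scenes: each scene has anchor
#' categories that appear with high probability (bed in bedrooms, oven /
#' sink in kitchens, couch / tv in living rooms) plus shared distractors
#' (person, chair, ...) appearing everywhere. Every category has a spatial
#' prior over the image (e.g. beds sit low and central), a Beta-distributed
#' confidence-score profile, and a small count distribution.
#'
#' @param anchors named list (per scene) of named vectors: anchor category
#'   presence probabilities.
#' @param distractors named vector of scene-independent presence
#'   probabilities.
#' @param spatial named list of `c(cx, cy, sd)` normalized center priors;
#'   categories not listed use `default`.
#' @param score_shape named list of Beta shape pairs for anchor and
#'   distractor scores.
#' @param extra_lambda Poisson rate of additional instances per present
#'   category.
#' @param image_size `c(width, height)` in pixels.
#' @return a `scene_sim_spec`.
#' @export
scene_sim_spec <- function(
    anchors = list(
      "kitchen" = c("oven" = 0.9, "microwave" = 0.7, "sink" = 0.8,
                    "refrigerator" = 0.6),
      "living room" = c("couch" = 0.9, "tv" = 0.85, "remote" = 0.5,
                        "vase" = 0.4),
      "bedroom" = c("bed" = 0.95, "clock" = 0.6, "book" = 0.5)),
    distractors = c("person" = 0.5, "chair" = 0.7, "potted plant" = 0.35,
                    "dining table" = 0.4),
    spatial = list(
      "bed" = c(0.5, 0.7, 0.10), "tv" = c(0.5, 0.3, 0.10),
      "couch" = c(0.5, 0.65, 0.12), "oven" = c(0.45, 0.6, 0.12),
      "sink" = c(0.55, 0.55, 0.12), "microwave" = c(0.5, 0.35, 0.10),
      "clock" = c(0.5, 0.2, 0.08), "default" = c(0.5, 0.5, 0.18)),
    score_shape = list(anchor = c(8, 2), distractor = c(5, 3)),
    extra_lambda = 0.3,
    image_size = c(640, 480)) {
  if (!all(names(anchors) %in% SCENES))
    stop("anchor scenes must be among: ", paste(SCENES, collapse = ", "))
  for (sc in names(anchors)) {
    p <- anchors[[sc]]
    if (any(p < 0 | p > 1)) stop("presence priors must be probabilities")
    coco_id(names(p))  # validates names
  }
  if (any(distractors < 0 | distractors > 1))
    stop("presence priors must be probabilities")
  structure(list(anchors = anchors, distractors = distractors,
                 spatial = spatial, score_shape = score_shape,
                 extra_lambda = extra_lambda, image_size = image_size),
            class = "scene_sim_spec")
}

sample_box <- function(spec, cat_name) {
  pr <- spec$spatial[[cat_name]]
  if (is.null(pr)) pr <- spec$spatial[["default"]]
  W <- spec$image_size[1]; H <- spec$image_size[2]
  cx <- min(max(rnorm(1, pr[1], pr[3]), 0.05), 0.95)
  cy <- min(max(rnorm(1, pr[2], pr[3]), 0.05), 0.95)
  bw <- runif(1, 0.10, 0.35) * W
  bh <- runif(1, 0.10, 0.35) * H
  c(x = max(cx * W - bw / 2, 0), y = max(cy * H - bh / 2, 0),
    w = bw, h = bh)
}

#' Generate scene-conditional synthetic detection sets
#'
#' For each image, samples which categories are present (scene anchors
#' plus shared distractors, independent Bernoulli draws from the priors),
#' an instance count per present category, box centers from the spatial
#' priors and confidence scores from the Beta profiles.
#'
#' @param spec a [scene_sim_spec()].
#' @param n_images number of images to generate.
#' @param scene scene name, one of `SCENES`.
#' @param seed RNG seed; `NULL` uses the current RNG state.
#' @return list of [detection_set()] objects.
#' @export
generate_detections <- function(spec, n_images, scene, seed = NULL) {
  stopifnot(inherits(spec, "scene_sim_spec"))
  if (!scene %in% SCENES) stop("unknown scene: ", scene)
  if (!is.null(seed)) set.seed(seed)
  anchors <- spec$anchors[[scene]]
  out <- vector("list", n_images)
  for (img in seq_len(n_images)) {
    rows <- list()
    cats <- c(anchors, spec$distractors)
    kinds <- c(rep("anchor", length(anchors)),
               rep("distractor", length(spec$distractors)))
    for (k in seq_along(cats)) {
      if (runif(1) > cats[k]) next
      nm <- names(cats)[k]
      cnt <- 1L + rpois(1, spec$extra_lambda)
      shape <- spec$score_shape[[kinds[k]]]
      for (inst in seq_len(cnt)) {
        box <- sample_box(spec, nm)
        rows[[length(rows) + 1]] <- data.frame(
          category = coco_id(nm), x = box["x"], y = box["y"],
          w = box["w"], h = box["h"],
          score = rbeta(1, shape[1], shape[2]))
      }
    }
    det <- if (length(rows) > 0) do.call(rbind, rows) else data.frame()
    out[[img]] <- detection_set(sprintf("%s_%04d", gsub(" ", "_", scene), img),
                                spec$image_size[1], spec$image_size[2], det)
  }
  out
}

#' Generate a balanced multi-scene detection dataset
#'
#' @param spec a [scene_sim_spec()].
#' @param n_per_scene images per scene.
#' @param seed RNG seed.
#' @return list with `detections` (list of [detection_set()]) and `labels`
#'   (scene names).
#' @export
generate_scene_dataset <- function(spec = scene_sim_spec(), n_per_scene = 100,
                                   seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  det <- list()
  labels <- character(0)
  for (sc in SCENES) {
    d <- generate_detections(spec, n_per_scene, sc, seed = NULL)
    det <- c(det, d)
    labels <- c(labels, rep(sc, n_per_scene))
  }
  list(detections = det, labels = labels)
}
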