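#' The 80 COCO object categories, in contiguous 0-based id order
#'
#' Category ids used by detection outputs trained on COCO (YOLO-style
#' contiguous 0..79 indexing).
#' @export
COCO_CATEGORIES <- c(
  "person", "bicycle", "car", "motorcycle", "airplane", "bus", "train",
  "truck", "boat", "traffic light", "fire hydrant", "stop sign",
  "parking meter", "bench", "bird", "cat", "dog", "horse", "sheep", "cow",
  "elephant", "bear", "zebra", "giraffe", "backpack", "umbrella", "handbag",
  "tie", "suitcase", "frisbee", "skis", "snowboard", "sports ball", "kite",
  "baseball bat", "baseball glove", "skateboard", "surfboard",
  "tennis racket", "bottle", "wine glass", "cup", "fork", "knife", "spoon",
  "bowl", "banana", "apple", "sandwich", "orange", "broccoli", "carrot",
  "hot dog", "pizza", "donut", "cake", "chair", "couch", "potted plant",
  "bed", "dining table", "toilet", "tv", "laptop", "mouse", "remote",
  "keyboard", "cell phone", "microwave", "oven", "toaster", "sink",
  "refrigerator", "book", "clock", "vase", "scissors", "teddy bear",
  "hair drier", "toothbrush")

#' Construct a per-image detection set
#'
#' @param image_id image identifier.
#' @param width,height image size in pixels (> 0).
#' @param detections data.frame with columns `category` (0-based id in
#'   0..C-1), `x`, `y`, `w`, `h` (bounding box, top-left origin, pixels)
#'   and `score` in `[0, 1]`. Boxes are clamped to the image bounds.
#' @param n_categories size of the category universe `C` (default 80).
#' @return a `detection_set`.
#' @export
detection_set <- function(image_id, width, height,
                          detections = data.frame(), n_categories = 80) {
  if (width <= 0 || height <= 0) stop("image must have positive area")
  det <- as.data.frame(detections)
  if (nrow(det) > 0) {
    need <- c("category", "x", "y", "w", "h", "score")
    if (!all(need %in% names(det)))
      stop("detections must have columns ", paste(need, collapse = ", "))
    if (any(det$category < 0 | det$category >= n_categories))
      stop("category id outside [0, ", n_categories, ")")
    if (any(det$score < 0 | det$score > 1))
      stop("detection scores must lie in [0, 1]")
    # clamp boxes to the image
    det$x <- pmin(pmax(det$x, 0), width)
    det$y <- pmin(pmax(det$y, 0), height)
    det$w <- pmin(det$w, width - det$x)
    det$h <- pmin(det$h, height - det$y)
  }
  structure(list(image_id = image_id, width = width, height = height,
                 detections = det, n_categories = as.integer(n_categories)),
            class = "detection_set")
}

#' @export
print.detection_set <- function(x, ...) {
  cat(sprintf("<detection_set> image %s (%dx%d), %d detections\n",
              x$image_id, x$width, x$height, nrow(x$detections)))
  invisible(x)
}

#' Category presence and count vectors
#'
#' @param ds a [detection_set()].
#' @return list with `pres` (binary, length C) and `cnt` (integer counts).
#' @export
build_presence_count <- function(ds) {
  stopifnot(inherits(ds, "detection_set"))
  cnt <- tabulate(ds$detections$category + 1L, ds$n_categories)
  list(pres = as.integer(cnt > 0), cnt = as.integer(cnt))
}

#' Mean confidence per category
#'
#' Arithmetic mean of detection scores per category; 0 for categories with
#' no detections.
#'
#' @param ds a [detection_set()].
#' @return numeric vector of length C.
#' @export
mean_confidence <- function(ds) {
  stopifnot(inherits(ds, "detection_set"))
  out <- numeric(ds$n_categories)
  if (nrow(ds$detections) == 0) return(out)
  agg <- tapply(ds$detections$score, ds$detections$category, mean)
  out[as.integer(names(agg)) + 1L] <- agg
  out
}

#' Grid confidence map
#'
#' Partitions the image into an N x N uniform grid, assigns each detection
#' to the cell containing its box center (normalized coordinates; cell
#' index `floor(N * c)`, clamped to N-1, so centers exactly on a boundary
#' fall in the higher cell), and sums the scores of each category's
#' detections per cell. Per-category maps are flattened row-major and
#' concatenated over categories.
#'
#' @param ds a [detection_set()].
#' @param n_grid grid resolution N (default 3).
#' @return numeric vector of length `C * N^2`.
#' @export
grid_confidence_map <- function(ds, n_grid = 3) {
  stopifnot(inherits(ds, "detection_set"))
  if (n_grid < 1) stop("n_grid must be >= 1")
  C <- ds$n_categories
  out <- numeric(C * n_grid^2)
  det <- ds$detections
  if (nrow(det) == 0) return(out)
  cx <- (det$x + det$w / 2) / ds$width
  cy <- (det$y + det$h / 2) / ds$height
  col <- pmin(pmax(floor(n_grid * cx), 0), n_grid - 1)
  row <- pmin(pmax(floor(n_grid * cy), 0), n_grid - 1)
  idx <- det$category * n_grid^2 + row * n_grid + col + 1
  for (i in seq_along(idx)) out[idx[i]] <- out[idx[i]] + det$score[i]
  out
}

#' Build the full structured scene feature vector
#'
#' Concatenates `[presence | count | mean confidence | grid map]` into a
#' vector of length `3C + C N^2` (960 with C = 80 categories and a 3 x 3
#' grid). Detections below `min_score` are dropped first.
#'
#' @param ds a [detection_set()].
#' @param n_grid grid resolution.
#' @param min_score confidence threshold for accepting detections.
#' @return numeric feature vector with attribute `"layout"` giving the
#'   block widths.
#' @export
build_scene_vector <- function(ds, n_grid = 3, min_score = 0.25) {
  stopifnot(inherits(ds, "detection_set"))
  keep <- ds$detections$score >= min_score
  ds$detections <- ds$detections[keep, , drop = FALSE]
  pc <- build_presence_count(ds)
  v <- c(pc$pres, pc$cnt, mean_confidence(ds),
         grid_confidence_map(ds, n_grid))
  attr(v, "layout") <- c(pres = ds$n_categories, cnt = ds$n_categories,
                         conf = ds$n_categories,
                         grid = ds$n_categories * n_grid^2)
  v
}

#' Featurize a list of detection sets
#'
#' @param ds_list list of [detection_set()] objects.
#' @inheritParams build_scene_vector
#' @return n_images x (3C + C N^2) feature matrix with the block layout in
#'   attribute `"layout"`.
#' @export
scene_featurize <- function(ds_list, n_grid = 3, min_score = 0.25) {
  rows <- lapply(ds_list, build_scene_vector, n_grid = n_grid,
                 min_score = min_score)
  out <- do.call(rbind, rows)
  attr(out, "layout") <- attr(rows[[1]], "layout")
  out
}

#' Read COCO-style detection results JSON
#'
#' Expects the standard detection-results layout: a JSON array of records
#' `{image_id, category_id, bbox = [x, y, w, h], score}` with 0-based
#' contiguous category ids. Image sizes are not part of that format, so
#' they are supplied through `image_sizes` (data.frame with columns
#' `image_id`, `width`, `height`) or fall back to `default_size`.
#'
#' @param path JSON file path.
#' @param image_sizes optional per-image size table.
#' @param default_size `c(width, height)` used when a size is not listed.
#' @param n_categories category universe size.
#' @return named list of [detection_set()], one per image id.
#' @export
read_coco_detections <- function(path, image_sizes = NULL,
                                 default_size = c(640, 480),
                                 n_categories = 80) {
  recs <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  for (i in seq_along(recs)) {
    r <- recs[[i]]
    if (is.null(r$image_id) || is.null(r$category_id) ||
        is.null(r$bbox) || is.null(r$score))
      stop(sprintf("detection record %d is missing required fields", i))
    if (length(r$bbox) != 4)
      stop(sprintf("detection record %d: bbox must have 4 elements", i))
    if (r$score < 0 || r$score > 1)
      stop(sprintf("detection record %d: score %.3f outside [0, 1]",
                   i, r$score))
    if (r$category_id < 0 || r$category_id >= n_categories)
      stop(sprintf("detection record %d: category id %d outside [0, %d)",
                   i, r$category_id, n_categories))
  }
  ids <- vapply(recs, function(r) as.character(r$image_id), "")
  out <- list()
  for (id in unique(ids)) {
    sub <- recs[ids == id]
    det <- data.frame(
      category = vapply(sub, function(r) as.numeric(r$category_id), 0),
      x = vapply(sub, function(r) as.numeric(r$bbox[[1]]), 0),
      y = vapply(sub, function(r) as.numeric(r$bbox[[2]]), 0),
      w = vapply(sub, function(r) as.numeric(r$bbox[[3]]), 0),
      h = vapply(sub, function(r) as.numeric(r$bbox[[4]]), 0),
      score = vapply(sub, function(r) as.numeric(r$score), 0))
    size <- default_size
    if (!is.null(image_sizes)) {
      hit <- match(id, as.character(image_sizes$image_id))
      if (!is.na(hit))
        size <- c(image_sizes$width[hit], image_sizes$height[hit])
    }
    out[[id]] <- detection_set(id, size[1], size[2], det, n_categories)
  }
  out
}

#' Write detection sets as COCO-style results JSON
#'
#' @param ds_list list of [detection_set()].
#' @param path output path.
#' @export
write_coco_detections <- function(ds_list, path) {
  recs <- list()
  for (ds in ds_list) {
    d <- ds$detections
    for (i in seq_len(nrow(d))) {
      recs[[length(recs) + 1]] <- list(
        image_id = ds$image_id, category_id = d$category[i],
        bbox = c(d$x[i], d$y[i], d$w[i], d$h[i]), score = d$score[i])
    }
  }
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
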