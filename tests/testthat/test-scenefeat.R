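det_row <- function(category, cx, cy, score, w = 60, h = 40,
                    width = 600, height = 300) {
  data.frame(category = category, x = cx * width - w / 2,
             y = cy * height - h / 2, w = w, h = h, score = score)
}

test_that("presence, count and mean confidence follow their definitions", {
  empty <- toy_detections(data.frame())
  pc <- build_presence_count(empty)
  expect_equal(pc$pres, rep(0L, 80))
  expect_equal(pc$cnt, rep(0L, 80))
  expect_equal(mean_confidence(empty), rep(0, 80))

  recs <- rbind(det_row(5, 0.2, 0.2, 0.6), det_row(5, 0.4, 0.4, 0.8),
                det_row(5, 0.6, 0.6, 0.9), det_row(10, 0.5, 0.5, 0.8))
  ds <- toy_detections(recs)
  pc <- build_presence_count(ds)
  expect_equal(pc$pres[6], 1L)
  expect_equal(pc$cnt[6], 3L)
  expect_equal(sum(pc$cnt), 4L)
  conf <- mean_confidence(ds)
  expect_equal(conf[6], mean(c(0.6, 0.8, 0.9)))
  expect_equal(conf[11], 0.8)
  expect_equal(conf[1], 0)       # absent category
  expect_length(c(pc$pres, pc$cnt), 160)

  expect_error(toy_detections(det_row(80, 0.5, 0.5, 0.5)), "category id")
  expect_error(toy_detections(det_row(3, 0.5, 0.5, 1.2)), "scores")
})

test_that("grid map assigns by box center with the floor/clamp convention", {
  # center of the image -> middle cell (1,1) of a 3x3 grid
  ds <- toy_detections(det_row(7, 0.5, 0.5, 0.8))
  g <- grid_confidence_map(ds, 3)
  m <- matrix(g[(7 * 9 + 1):(7 * 9 + 9)], 3, 3, byrow = TRUE)
  expect_equal(m[2, 2], 0.8)
  expect_equal(sum(g), 0.8)

  # center exactly on the 1/3 boundary goes to the higher cell index
  ds2 <- toy_detections(det_row(0, 1 / 3, 0.1, 0.5))
  g2 <- grid_confidence_map(ds2, 3)
  m2 <- matrix(g2[1:9], 3, 3, byrow = TRUE)
  expect_equal(m2[1, 2], 0.5)

  # per-category mass conservation on a random detection set
  set.seed(8)
  recs <- data.frame(category = sample(0:79, 40, TRUE),
                     x = runif(40, 0, 560), y = runif(40, 0, 260),
                     w = runif(40, 5, 40), h = runif(40, 5, 40),
                     score = runif(40))
  ds3 <- toy_detections(recs)
  g3 <- grid_confidence_map(ds3, 3)
  for (c in unique(recs$category)) {
    expect_equal(sum(g3[(c * 9 + 1):(c * 9 + 9)]),
                 sum(ds3$detections$score[ds3$detections$category == c]),
                 tolerance = 1e-12)
  }
})

test_that("the full scene vector has the documented layout", {
  recs <- rbind(det_row(59, 0.5, 0.7, 0.9), det_row(0, 0.3, 0.4, 0.7))
  v <- build_scene_vector(toy_detections(recs))
  expect_length(v, 960)
  expect_equal(unname(attr(v, "layout")), c(80, 80, 80, 720))
  expect_equal(sum(attr(v, "layout")[1:3]), 240)
  expect_equal(as.vector(build_scene_vector(toy_detections(data.frame()))),
               rep(0, 960))
  # sub-threshold detections are dropped
  weak <- build_scene_vector(toy_detections(det_row(3, 0.5, 0.5, 0.1)))
  expect_equal(as.vector(weak), rep(0, 960))
})

test_that("scene features are scale- and order-invariant", {
  recs <- rbind(det_row(59, 0.5, 0.7, 0.9), det_row(62, 0.2, 0.3, 0.8),
                det_row(0, 0.8, 0.8, 0.6))
  ds <- toy_detections(recs)
  v1 <- build_scene_vector(ds)

  big <- recs
  big[, c("x", "y", "w", "h")] <- big[, c("x", "y", "w", "h")] * 2.5
  v2 <- build_scene_vector(toy_detections(big, width = 1500, height = 750))
  expect_equal(v1, v2, tolerance = 1e-12)

  v3 <- build_scene_vector(toy_detections(recs[c(3, 1, 2), ]))
  expect_equal(v1, v3, tolerance = 1e-12)

  # removing one detection removes exactly its count and score mass
  v4 <- build_scene_vector(toy_detections(recs[-1, ]))
  expect_equal(sum(v1[81:160]) - sum(v4[81:160]), 1)
  expect_equal(sum(v1[241:960]) - sum(v4[241:960]), 0.9, tolerance = 1e-12)
})

test_that("COCO detection JSON round-trips and is validated", {
  recs <- rbind(det_row(59, 0.5, 0.7, 0.9), det_row(0, 0.3, 0.4, 0.7))
  ds <- toy_detections(recs)
  path <- tempfile(fileext = ".json")
  write_coco_detections(list(ds), path)
  back <- read_coco_detections(path, default_size = c(600, 300))
  expect_length(back, 1)
  expect_equal(back[["img1"]]$detections$score, recs$score)
  expect_equal(back[["img1"]]$detections$category, recs$category)
  expect_equal(build_scene_vector(back[["img1"]]), build_scene_vector(ds),
               tolerance = 1e-12)

  bad <- tempfile(fileext = ".json")
  writeLines(paste0('[{"image_id": 1, "category_id": 3,',
                    ' "bbox": [10, 10, 50, 50], "score": 1.2}]'), bad)
  expect_error(read_coco_detections(bad), "outside \\[0, 1\\]")
  writeLines('[{"image_id": 1, "category_id": 3, "score": 0.5}]', bad)
  expect_error(read_coco_detections(bad), "missing required fields")
})
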