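scene_fixture <- function(n_per_scene = 30, seed = 7) {
  d <- generate_scene_dataset(scene_sim_spec(), n_per_scene, seed = seed)
  list(x = scene_featurize(d$detections), y = d$labels)
}

test_that("scene classifier learns separable synthetic scenes", {
  fx <- scene_fixture()
  sp <- stratified_split(fx$y, 0.7, 1)
  m <- fit_scene(fx$x[sp$train, ], fx$y[sp$train], seed = 1)
  pred <- predict_scene(m, fx$x[sp$test, ])
  expect_gt(mean(pred$scene_name == fx$y[sp$test]), 2 / 3)
  expect_equal(rowSums(pred$p_scene), rep(1, length(sp$test)),
               tolerance = 1e-12)
  # an all-zero feature row still yields a valid probability vector
  p0 <- predict_scene(m, matrix(0, 1, ncol(fx$x)))
  expect_equal(sum(p0$p_scene), 1, tolerance = 1e-12)
  expect_true(p0$scene %in% 0:2)
})

test_that("scene fitting validates inputs and clips the PCA dimension", {
  fx <- scene_fixture(n_per_scene = 10)
  one <- fx$y == "kitchen"
  expect_error(fit_scene(fx$x[one, ], fx$y[one]), "at least two scenes")
  expect_warning(fit_scene(fx$x, fx$y, pca_dim = 500, cv_folds = 3),
                 "clipped")
})

test_that("scene predictions are reproducible under a fixed seed", {
  fx <- scene_fixture(n_per_scene = 15)
  sp <- stratified_split(fx$y, 0.7, 2)
  m1 <- fit_scene(fx$x[sp$train, ], fx$y[sp$train], pca_dim = 20,
                  cv_folds = 3, seed = 5)
  m2 <- fit_scene(fx$x[sp$train, ], fx$y[sp$train], pca_dim = 20,
                  cv_folds = 3, seed = 5)
  p1 <- predict_scene(m1, fx$x[sp$test, ])
  p2 <- predict_scene(m2, fx$x[sp$test, ])
  expect_identical(p1$scene, p2$scene)
  expect_equal(p1$p_scene, p2$p_scene)
})

test_that("the ablation harness mirrors the documented combinations", {
  fx <- scene_fixture(n_per_scene = 25, seed = 9)
  tab <- ablation_harness(fx$x, fx$y, seed = 3)
  expect_equal(nrow(tab), 3)
  expect_equal(tab$dim, c(160, 240, 50))
  expect_true(all(tab$accuracy > 1 / 3))          # every combo beats chance
  expect_true(all(tab$f1 >= 0 & tab$f1 <= 1))
})

test_that("adding the grid block never hurts training-set fit", {
  fx <- scene_fixture(n_per_scene = 20, seed = 10)
  y <- fx$y
  m_nogrid <- fit_scene(fx$x[, 1:240], y, pca_dim = NULL, seed = 4)
  m_full <- fit_scene(fx$x, y, pca_dim = 50, seed = 4)
  acc_nogrid <- mean(predict_scene(m_nogrid, fx$x[, 1:240])$scene_name == y)
  acc_full <- mean(predict_scene(m_full, fx$x)$scene_name == y)
  expect_gte(acc_full, acc_nogrid - 1e-9)
})
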