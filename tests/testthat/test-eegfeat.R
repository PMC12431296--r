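test_that("CSP solves the 2x2 problem in closed form", {
  W <- csp_fit(diag(c(2, 1)), diag(c(1, 2)), shrinkage = 0)
  ev <- attr(W, "eigenvalues")
  expect_equal(ev, c(2 / 3, 1 / 3), tolerance = 1e-12)
  # first filter picks out channel 1 (up to sign)
  expect_equal(abs(W[, 1] / sqrt(sum(W[, 1]^2))), c(1, 0), tolerance = 1e-12)
})

test_that("CSP degenerates gracefully when the classes are identical", {
  C <- rand_spd(4, seed = 3)
  W <- csp_fit(C, C, shrinkage = 0)
  expect_equal(attr(W, "eigenvalues"), rep(0.5, 4), tolerance = 1e-10)
})

test_that("CSP filters satisfy the whitening constraint", {
  for (seed in 1:3) {
    C1 <- rand_spd(6, seed)
    C2 <- rand_spd(6, seed + 100)
    W <- csp_fit(C1, C2, shrinkage = 0)
    expect_lt(max(abs(t(W) %*% (C1 + C2) %*% W - diag(6))), 1e-8)
  }
})

test_that("FBCSP features have the documented width and normalization", {
  ep <- toy_epochs(n_per_class = 4, n_ch = 6, n_samp = 750, seed = 21)
  ep$fs <- 250
  wp <- window_par(2, 0.5, 0, 3)
  model <- fbcsp_fit(ep, filter_bank(), wp)
  f <- model$features
  expect_equal(ncol(f), 44)
  expect_equal(nrow(f), 16 * 3)           # 3 windows per trial
  # per band the 4 log-variance-ratio features satisfy sum(exp(f)) = 1
  for (b in 1:11) {
    block <- f[, (4 * b - 3):(4 * b), drop = FALSE]
    expect_equal(rowSums(exp(block)), rep(1, nrow(f)), tolerance = 1e-12)
  }
})

test_that("FBCSP features are invariant to common positive channel scaling", {
  ep <- toy_epochs(n_per_class = 3, n_ch = 4, n_samp = 750, seed = 22)
  wp <- window_par(2, 1, 0, 3)
  model <- fbcsp_fit(ep, filter_bank(), wp)
  scaled <- ep
  scaled$data <- ep$data * 5.5
  f1 <- fbcsp_features(ep, model = model)
  f2 <- fbcsp_features(scaled, model = model)
  expect_equal(f1, f2, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("wavelet-packet energies conserve energy and localize frequency", {
  expect_equal(as.vector(wpd_energy(rep(0, 512))), rep(0, 6))

  set.seed(41)
  x <- rnorm(512)
  leaves <- wpd_energy(x, all_leaves = TRUE)
  expect_equal(sum(leaves), sum(x^2), tolerance = 1e-6 * sum(x^2))
  expect_lte(sum(wpd_energy(x)), sum(leaves))

  # 10 Hz sine at fs 250: leaf width 125/32 Hz, so 10 Hz sits in leaf 2
  t <- (0:511) / 250
  s <- sin(2 * pi * 10 * t)
  e <- wpd_energy(s, all_leaves = TRUE)
  expect_equal(which.max(e) - 1L, 2L)

  expect_error(wpd_energy(rnorm(16)), "shorter than the decomposition")
})

test_that("sample entropy matches the brute-force counting oracle", {
  x <- rep(c(1, 2, 3), 33)
  r <- 0.5 * sd(x)
  expect_equal(sample_entropy(x, 2, r), sampen_naive(x, 2, r),
               tolerance = 1e-12)
  set.seed(52)
  y <- runif(200)
  r <- 0.2 * sd(y)
  expect_equal(sample_entropy(y, 2, r), sampen_naive(y, 2, r),
               tolerance = 1e-12)
  expect_equal(sample_entropy(rep(5, 60), 2, 0.5), 0)
  expect_error(sample_entropy(c(1, 2), 2, 0.5), "too short")
})

test_that("noise is more entropic than a matched sine", {
  set.seed(63)
  t <- (0:499) / 250
  sine <- sin(2 * pi * 10 * t)
  noise <- rnorm(500, sd = sd(sine))
  expect_gt(sample_entropy(noise, 2, 0.2 * sd(noise)),
            sample_entropy(sine, 2, 0.2 * sd(sine)))
})

test_that("spectral entropy matches direct summation and its anchors", {
  # equal power in 8 distinct bins -> 3 bits
  n <- 256
  t <- (0:(n - 1)) / n
  x <- rowSums(sapply(1:8, function(k) sin(2 * pi * 10 * k * t)))
  expect_equal(spectral_entropy(x), 3, tolerance = 1e-9)
  # all power in one bin -> 0 bits
  expect_equal(spectral_entropy(sin(2 * pi * 10 * t)), 0, tolerance = 1e-9)

  set.seed(74)
  y <- rnorm(300)
  pw <- Mod(fft(y))^2
  p <- pw[2:151] / sum(pw[2:151])
  expect_equal(spectral_entropy(y), -sum(p * log2(p)), tolerance = 1e-12)
  expect_error(spectral_entropy(rep(0, 100)), "all-zero")
})

test_that("Higuchi fractal dimension separates lines from noise", {
  expect_equal(fractal_dimension(seq_len(1000)), 1, tolerance = 0.05)
  set.seed(85)
  expect_equal(fractal_dimension(rnorm(1000)), 2, tolerance = 0.1)
  expect_error(fractal_dimension(rep(1, 100)), "constant")
})

test_that("feature assembly concatenates, compresses and standardizes", {
  set.seed(96)
  blocks <- list(fbcsp = matrix(rnorm(60 * 44), 60),
                 wpd = matrix(rnorm(60 * 90), 60),
                 nl = matrix(rnorm(60 * 45), 60))
  asm <- assemble_features(blocks)
  expect_equal(sum(asm$block_widths), 179)
  expect_equal(unname(asm$block_widths), c(44, 90, 45))
  tf <- asm$features
  expect_equal(unname(colMeans(tf)), rep(0, ncol(tf)), tolerance = 1e-9)
  expect_equal(unname(apply(tf, 2, sd)), rep(1, ncol(tf)), tolerance = 1e-9)
  expect_gte(asm$state$explained, 0.95)

  # reusing the fitted state is a pure transform
  again <- assemble_features(blocks, state = asm$state)
  expect_equal(again$features, tf)
  expect_error(apply_feature_state(list(), matrix(0, 1, 179)),
               "not a fitted")
  expect_error(assemble_features(list(a = matrix(0, 2, 3),
                                      b = matrix(0, 3, 3))), "same number")
})

test_that("PCA on exactly orthogonal columns recovers their variances", {
  n <- 40
  x0 <- scale(matrix(rnorm(n * 3), n), center = TRUE, scale = FALSE)
  u <- svd(x0)$u                               # orthonormal, zero-mean columns
  sds <- c(3, 2, 1)
  x <- sweep(u, 2, sds * sqrt(n - 1), "*")     # column sd exactly sds
  st <- fit_feature_state(x, var_explained = 1)
  expect_equal(st$evr, sds^2 / sum(sds^2), tolerance = 1e-8)
})
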