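test_that("discriminative variance score matches a direct arithmetic oracle", {
  ep <- toy_epochs(n_per_class = 5, n_ch = 3, n_samp = 80,
                   sd_by_class = c(2, 1, 1, 1), seed = 11)
  eps <- 1e-10
  for (ch in 1:3) {
    x <- ep$data[, ch, ]
    pooled <- var(as.vector(x))
    oracle <- mean(vapply(0:3, function(j) {
      xj <- x[ep$labels == j, , drop = FALSE]
      mean(apply(xj, 1, var)) / (pooled + eps)
    }, 0))
    expect_equal(discriminative_variance_score(ep, ch, eps), oracle,
                 tolerance = 1e-12)
  }
})

test_that("variance score hits its analytic anchors", {
  # identical trials: every class variance equals the pooled variance
  base <- matrix(rnorm(60, sd = 2), 1, 60)
  data <- array(rep(base, each = 8), dim = c(8, 1, 60))
  for (tr in 1:8) data[tr, 1, ] <- base
  ep <- eeg_epochs(data, rep(0:3, 2), 250, "c1", 0)
  expect_lt(abs(discriminative_variance_score(ep, 1) - 1), 0.02)

  # silent channel scores zero
  ep$data[, 1, ] <- 0
  expect_equal(discriminative_variance_score(ep, 1), 0)
})

test_that("ANOVA power score equals the closed-form F-test oracle", {
  set.seed(31)
  # trials engineered so P_t = mean(x^2) is an exact planted value
  powers <- abs(rnorm(40, mean = rep(c(1, 1.6, 1, 1), 10), sd = 0.2))
  labels <- rep(0:3, 10)
  data <- array(0, dim = c(40, 1, 50))
  for (tr in 1:40) data[tr, 1, ] <- sqrt(powers[tr])
  ep <- eeg_epochs(data, labels, 250, "c1", 0)

  # textbook one-way ANOVA on the planted powers
  k <- 4; n <- 40
  gm <- mean(powers)
  mim <- tapply(powers, labels, mean)
  ssb <- sum(table(labels) * (mim - gm)^2)
  ssw <- sum((powers - mim[as.character(labels)])^2)
  Fstat <- (ssb / (k - 1)) / (ssw / (n - k))
  p <- pf(Fstat, k - 1, n - k, lower.tail = FALSE)
  expect_equal(anova_power_score(ep, 1), -log10(p), tolerance = 1e-9)
})

test_that("degenerate power distributions give a zero score with warning", {
  data <- array(1, dim = c(8, 1, 30))
  ep <- eeg_epochs(data, rep(0:3, 2), 250, "c1", 0)
  expect_warning(s <- anova_power_score(ep, 1), "identical")
  expect_equal(s, 0)
})

test_that("fusion honours alpha, min-max anchors, and the core guarantee", {
  tab <- data.frame(
    channel = c("C3", "Cz", "C4", paste0("X", 1:6)),
    is_core = c(TRUE, TRUE, TRUE, rep(FALSE, 6)),
    s_var = c(0, 0, 0, 5, 4, 3, 2, 1, 0.5),
    s_anova = c(0, 0, 0, 0.5, 1, 2, 3, 4, 5))
  cfg <- selection_config(k_total = 6, alpha = 1)
  sel <- fuse_and_select(tab, cfg)
  expect_equal(sel[1:3], c("C3", "Cz", "C4"))
  expect_equal(sel[4:6], c("X1", "X2", "X3"))   # pure variance ranking
  t2 <- attr(sel, "table")
  expect_equal(max(t2$s_var_norm, na.rm = TRUE), 1)
  expect_equal(min(t2$s_var_norm, na.rm = TRUE), 0)
  expect_equal(t2$s_var_norm[4], 1)             # best candidate
  expect_equal(t2$s_var_norm[9], 0)             # worst candidate

  cfg0 <- selection_config(k_total = 6, alpha = 0)
  sel0 <- fuse_and_select(tab, cfg0)
  expect_equal(sel0[4:6], c("X6", "X5", "X4"))  # pure ANOVA ranking

  # core channels retained even though their raw scores are worst
  expect_true(all(c("C3", "Cz", "C4") %in% sel))
  expect_length(sel, 6)
})

test_that("a degenerate score column falls back to the other criterion", {
  tab <- data.frame(
    channel = c("C3", "Cz", "C4", "A", "B", "D"),
    is_core = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
    s_var = c(0, 0, 0, 2, 2, 2),          # uninformative
    s_anova = c(0, 0, 0, 1, 3, 2))
  sel <- fuse_and_select(tab, selection_config(k_total = 5))
  expect_equal(sel[4:5], c("B", "D"))
  expect_equal(attr(sel, "table")$s_var_norm[4:6], rep(0, 3))
})

test_that("scores are invariant to trial order", {
  ep <- toy_epochs(n_per_class = 4, n_ch = 2, n_samp = 60, seed = 5)
  set.seed(9)
  perm <- sample(n <- dim(ep$data)[1])
  ep2 <- ep
  ep2$data <- ep$data[perm, , , drop = FALSE]
  ep2$labels <- ep$labels[perm]
  for (ch in 1:2) {
    expect_equal(discriminative_variance_score(ep, ch),
                 discriminative_variance_score(ep2, ch), tolerance = 1e-12)
    expect_equal(anova_power_score(ep, ch),
                 anova_power_score(ep2, ch), tolerance = 1e-12)
  }
})

test_that("channel selection recovers planted ERD channels", {
  fx <- recovery_sim_spec()
  ep <- generate_mi_eeg(fx$spec, 96, seed = 101)
  epf <- baseline_correct(bandpass_filter(ep))
  sel <- select_mi_channels(neurointent:::crop_epochs(epf, 1, 4))
  expect_true(all(fx$planted %in% sel))
  expect_true(all(c("C3", "Cz", "C4") %in% sel))
  expect_length(sel, 15)
})
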