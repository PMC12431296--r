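test_that("the EEG generator honours its contract and is seed-deterministic", {
  spec <- eeg_sim_spec()
  ep1 <- generate_mi_eeg(spec, 12, seed = 3)
  expect_equal(dim(ep1$data), c(12, 22, round(4.8 * 250)))
  expect_equal(sort(tabulate(ep1$labels + 1, 4)), rep(3, 4))
  ep2 <- generate_mi_eeg(spec, 12, seed = 3)
  expect_identical(ep1$data, ep2$data)
  expect_identical(ep1$labels, ep2$labels)
  ep3 <- generate_mi_eeg(spec, 12, seed = 4)
  expect_false(identical(ep1$data, ep3$data))

  expect_error(eeg_sim_spec(erd = list("left hand" = c(C3 = 1.5))),
               "attenuations")
  expect_error(eeg_sim_spec(erd = list("left hand" = c(Qq9 = 0.5))),
               "unknown channel")
})

test_that("measured mu-band ERD matches the configured attenuation", {
  # noise-free spec isolates the rhythm modulation
  att <- 0.6
  spec <- eeg_sim_spec(noise_sd = 1e-6,
                       erd = list("left hand" = c(C4 = att),
                                  "right hand" = c(C3 = att)))
  ep <- generate_mi_eeg(spec, 24, seed = 11)
  c4 <- which(ep$channel_names == "C4")
  t_img <- round((c(1.5, 4) - ep$t_start) * ep$fs)    # fully inside imagery
  idx <- (t_img[1] + 1):t_img[2]
  p_left <- mean(sapply(which(ep$labels == 0), function(tr)
    band_power(ep$data[tr, c4, idx], ep$fs, c(8, 13))))
  p_other <- mean(sapply(which(ep$labels == 2), function(tr)
    band_power(ep$data[tr, c4, idx], ep$fs, c(8, 13))))
  drop <- 1 - sqrt(p_left / p_other)    # amplitude-scale attenuation
  expect_lt(abs(drop - att) / att, 0.1)
})

test_that("zero attenuation makes the classes statistically exchangeable", {
  spec <- eeg_sim_spec(erd = list("left hand" = c(C4 = 0),
                                  "right hand" = c(C3 = 0)))
  ep <- generate_mi_eeg(spec, 32, seed = 21)
  epf <- bandpass_filter(ep)
  # no channel should show significant class structure in band power
  scores <- vapply(c("C3", "C4", "Cz", "CP3"), function(ch)
    anova_power_score(neurointent:::crop_epochs(epf, 1, 4), ch), 0)
  expect_true(all(scores < 2))          # -log10(p) < 2, i.e. p > 0.01
})

test_that("the detection generator follows its presence priors", {
  spec <- scene_sim_spec(
    anchors = list(bedroom = c(bed = 1.0, clock = 0.5)),
    distractors = c(person = 0.3))
  ds <- generate_detections(spec, 60, "bedroom", seed = 5)
  bed_id <- which(COCO_CATEGORIES == "bed") - 1
  has_bed <- vapply(ds, function(d) bed_id %in% d$detections$category, TRUE)
  expect_true(all(has_bed))             # prior 1.0 anchor always present
  expect_error(generate_detections(spec, 5, "garage"), "unknown scene")

  # empirical frequencies inside the exact 95% binomial band at n = 500
  ds2 <- generate_detections(scene_sim_spec(), 500, "kitchen", seed = 6)
  pri <- scene_sim_spec()$anchors$kitchen
  for (nm in names(pri)) {
    cid <- which(COCO_CATEGORIES == nm) - 1
    k <- sum(vapply(ds2, function(d) cid %in% d$detections$category, TRUE))
    lo <- qbinom(0.025, 500, pri[[nm]])
    hi <- qbinom(0.975, 500, pri[[nm]])
    expect_gte(k, lo)
    expect_lte(k, hi)
  }
})

test_that("detection generation is seed-deterministic", {
  spec <- scene_sim_spec()
  d1 <- generate_detections(spec, 5, "living room", seed = 12)
  d2 <- generate_detections(spec, 5, "living room", seed = 12)
  expect_identical(lapply(d1, `[[`, "detections"),
                   lapply(d2, `[[`, "detections"))
})
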