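test_that("individual profiles: lambda = 0 degeneracy and determinism", {
  g <- group_profile("g", 1)
  p0 <- sample_individual_profile(g, 0, seed = 5)
  expect_identical(p0$freq_multiplier, 1)
  expect_identical(p0$amplitude_multiplier, 1)
  expect_identical(p0$orientation_offset, c(0, 0, 0))

  p1 <- sample_individual_profile(g, 0.5, seed = 9, individual_id = "x")
  p2 <- sample_individual_profile(g, 0.5, seed = 9, individual_id = "x")
  expect_identical(p1, p2)
  p3 <- sample_individual_profile(g, 0.5, seed = 10)
  expect_false(p3$freq_multiplier == p1$freq_multiplier)
  expect_gt(p1$freq_multiplier, 0)
  expect_gt(p1$amplitude_multiplier, 0)

  expect_error(sample_individual_profile(g, -0.1, seed = 1),
               class = "ethocv_validation_error")
  expect_error(group_profile("g", size_scale = 0),
               class = "ethocv_validation_error")
})

test_that("profile multipliers follow the stated log-normal spread", {
  # Monte-Carlo check: sd of log(freq_multiplier) ~ freq_sigma * lambda
  g <- group_profile("g", 1)
  lam <- 0.5
  draws <- vapply(1:1000, function(i)
    log(sample_individual_profile(g, lam, seed = i,
                                  freq_sigma = 0.25)$freq_multiplier), 0.0)
  expect_lt(abs(sd(draws) - 0.25 * lam) / (0.25 * lam), 0.10)
  expect_lt(abs(mean(draws)), 0.02)
})

test_that("behaviour model validation enforces the structural invariants", {
  expect_error(behaviour_model("gallop", c(0, 0, 1), 1, c(0.1, 0.1, 0.1), 0.01),
               class = "ethocv_class_error")
  expect_error(behaviour_model("walk", c(0, 0, 2), 1, c(0.1, 0.1, 0.1), 0.01),
               class = "ethocv_validation_error")
  m <- default_behaviour_models()
  expect_named(m, ethogram_classes(), ignore.order = TRUE)
  # gait frequency ordering is what classification of locomotion rests on
  expect_lt(m$walk$osc_frequency, m$trot$osc_frequency)
  expect_lt(m$trot$osc_frequency, m$run$osc_frequency)
  broken <- m
  broken$trot <- behaviour_model("trot", c(0, 0, 1), 5.0, c(0.3, 0.2, 0.45),
                                 0.05)
  expect_error(validate_behaviour_models(broken),
               class = "ethocv_validation_error")
})

test_that("generate_recording: length bookkeeping and label tiling", {
  g <- group_profile("g", 1)
  p <- sample_individual_profile(g, 0, seed = 1, individual_id = "i1")
  meta <- recording_meta("i1", "g")
  out <- generate_recording(p, g, ethogram_script("stand", 10), meta,
                            seed = 3)
  expect_equal(nrow(out$recording), 500)  # 10 s at 50 Hz
  expect_equal(nrow(out$labels), 1)
  expect_equal(out$labels$start_s, 0)
  expect_equal(out$labels$end_s, 10)

  # multi-interval script: labels tile the scripted durations exactly and
  # every sample falls in exactly one half-open interval
  script <- ethogram_script(c("walk", "run", "eat"), c(3.5, 2.5, 4))
  out2 <- generate_recording(p, g, script, meta, seed = 3)
  expect_equal(out2$labels$start_s, c(0, 3.5, 6))
  expect_equal(out2$labels$end_s, c(3.5, 6, 10))
  hits <- vapply(out2$recording$t, function(tt)
    sum(tt >= out2$labels$start_s & tt < out2$labels$end_s), 0L)
  expect_true(all(hits == 1L))

  expect_error(generate_recording(p, g, ethogram_script("walk", -1), meta, 1),
               class = "ethocv_validation_error")
})

test_that("oscillation frequency survives into the periodogram", {
  # zero-noise run: the dominant periodogram frequency of the acceleration
  # magnitude must equal the profile- and group-scaled run frequency
  # within one frequency bin
  models <- default_behaviour_models()
  models$run <- behaviour_model("run", c(0, 0, 1), 3.5, c(0.5, 0.35, 0.8), 0)
  g <- group_profile("g", size_scale = 1.25)
  p <- sample_individual_profile(g, 0.5, seed = 21, individual_id = "i1")
  out <- generate_recording(p, g, ethogram_script("run", 20),
                            recording_meta("i1", "g"), seed = 2,
                            models = models)
  acc <- as.matrix(out$recording[, c("ax", "ay", "az")])
  mag <- sqrt(rowSums(acc^2))
  n <- length(mag)
  spec <- Mod(fft(mag - mean(mag)))^2
  k <- which.max(spec[2:floor(n / 2)])
  dom <- k * 50 / n
  f_expected <- 3.5 * p$freq_multiplier / g$size_scale
  expect_lt(abs(dom - f_expected), 50 / n + 1e-9)
})

test_that("lambda = 0 individuals are exchangeable given the same stream", {
  g <- group_profile("g", 1)
  p1 <- sample_individual_profile(g, 0, seed = 1, individual_id = "a")
  p2 <- sample_individual_profile(g, 0, seed = 99, individual_id = "b")
  meta1 <- recording_meta("a", "g"); meta2 <- recording_meta("b", "g")
  r1 <- generate_recording(p1, g, default_script(4), meta1, seed = 5)
  r2 <- generate_recording(p2, g, default_script(4), meta2, seed = 5)
  expect_equal(as.data.frame(r1$recording), as.data.frame(r2$recording),
               ignore_attr = TRUE)
})

test_that("generate_cohort: ids, determinism, n >= 2", {
  g <- group_profile("grp", 1)
  coh <- generate_cohort(7, g, default_script(3), 0.4, seed = 13)
  ids <- vapply(coh, function(x) x$profile$individual_id, "")
  expect_length(unique(ids), 7)
  expect_error(generate_cohort(1, g, default_script(3), 0.4, seed = 13),
               class = "ethocv_validation_error")

  coh2 <- generate_cohort(7, g, default_script(3), 0.4, seed = 13)
  expect_identical(coh, coh2)
})

test_that("lambda = 0 washes out individual differences; large lambda does not", {
  # with no individual effect, the same window feature has the same
  # distribution for every animal (location test does not reject at a
  # loose level); with a strong effect, individuals are identifiable
  # above chance from features alone
  ds0 <- test_dataset(n_ind = 3, dur = 6, lambda = 0, seed = 31,
                      behaviours = c("walk", "run"))
  f <- ds0$features[, "dom_freq_acc"]
  ids <- unique(ds0$individual_id)
  pv <- t.test(f[ds0$individual_id == ids[1]],
               f[ds0$individual_id == ids[2]])$p.value
  expect_gt(pv, 0.01)

  ds1 <- test_dataset(n_ind = 3, dur = 6, lambda = 1, seed = 31,
                      behaviours = c("walk", "run"))
  ident <- structure(list(features = ds1$features,
                          labels = ds1$individual_id,
                          individual_id = ds1$individual_id,
                          group_id = ds1$group_id,
                          feature_names = ds1$feature_names),
                     class = "feature_dataset")
  folds <- make_random_folds(ident, cv_config("random", n_repeats = 2,
                                              seed = 3))
  rep <- cross_validate(ident, default_test_params(), folds)
  expect_gt(rep$mean, 2 / length(unique(ds1$individual_id)))
})
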