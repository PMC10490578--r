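test_that("generation is fully deterministic under the seed", {
  cfg <- sim_config(n_gestures = 2, samples_per_gesture = 3,
                    n_seatings = 2, length_range = c(20L, 30L), seed = 77)
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(a$dataset$samples, b$dataset$samples)
  expect_identical(a$powergrips, b$powergrips)
  expect_identical(a$seating_offsets, b$seating_offsets)
})

test_that("templates are smooth, non-negative and distinct across labels", {
  cfg <- sim_config(seed = 5)
  t1 <- make_template(1, cfg)
  t2 <- make_template(2, cfg)
  expect_true(all(t1 >= 0))
  expect_false(identical(unclass(t1), unclass(t2)))
  expect_identical(unclass(make_template(1, cfg)), unclass(t1))
  expect_equal(attr(t1, "label"), "g01")
})

test_that("noise-free, jitter-free samples reproduce the template exactly", {
  cfg <- sim_config(noise_sigma = 0, amplitude_jitter = 0, time_jitter = 0,
                    length_range = c(30L, 30L), seed = 9)
  tpl <- make_template(1, cfg)
  set.seed(1)
  smp <- sample_gesture(tpl, cfg)
  expect_equal(smp, unclass(tpl), ignore_attr = TRUE)
  expect_equal(normalized_dtw(smp, unclass(tpl)), 0)
})

test_that("noise and time jitter perturb distance and length", {
  cfg <- sim_config(noise_sigma = 0.05, time_jitter = 0.2,
                    length_range = c(40L, 60L), seed = 9)
  tpl <- make_template(1, cfg)
  set.seed(2)
  lens <- replicate(12, ncol(sample_gesture(tpl, cfg)))
  expect_gt(length(unique(lens)), 1L)
  set.seed(3)
  expect_gt(normalized_dtw(sample_gesture(tpl, cfg), unclass(tpl)), 0)
})

test_that("dataset shapes match the configuration exactly", {
  multi <- simulate_dataset(sim_config(n_gestures = 7,
                                       samples_per_gesture = 20,
                                       n_seatings = 5,
                                       length_range = c(20L, 30L),
                                       seed = 1))
  expect_equal(n_samples(multi$dataset), 700L)
  per_seating <- table(multi$dataset$info$seating)
  expect_equal(as.vector(per_seating), rep(140L, 5))
  expect_equal(length(multi$seating_offsets), 5L)
  expect_equal(multi$seating_offsets[1], 0)
})

test_that("without re-seating or noise all samples equal up to length jitter", {
  sim <- simulate_dataset(sim_config(n_gestures = 1, samples_per_gesture = 4,
                                     n_seatings = 2, noise_sigma = 0,
                                     amplitude_jitter = 0, time_jitter = 0,
                                     seating_rotation = 0,
                                     length_range = c(25L, 25L), seed = 6))
  s <- sim$dataset$samples
  for (i in 2:4) expect_equal(s[[i]], s[[1]])
})

test_that("powergrip recordings plateau near the per-channel MVC level", {
  cfg <- sim_config(n_gestures = 1, samples_per_gesture = 1,
                    noise_sigma = 0.02, mvc_level = 2, seed = 11)
  sim <- simulate_dataset(cfg)
  f <- powergrip_factors(sim$powergrips)
  # plateau levels were drawn in mvc_level * [0.8, 1.2]
  expect_true(all(f$per_sensor > 1.5 & f$per_sensor < 2.5))
})

test_that("degrading the signal-to-noise ratio degrades accuracy", {
  acc_at <- function(noise) {
    sim <- simulate_dataset(sim_config(n_gestures = 3,
                                       samples_per_gesture = 8,
                                       length_range = c(30L, 45L),
                                       noise_sigma = noise, seed = 21))
    sp <- make_splits(sim$dataset,
                      split_plan("random_fraction", repeats = 1, seed = 2))[[1]]
    evaluate_classifier(sp$test,
                        build_reference_set(sp$reference, "uncondensed"))$alpha
  }
  lo <- acc_at(0.05); hi <- acc_at(2.5)
  expect_equal(lo, 1)
  expect_lt(hi, lo)
})

test_that("identical sequences have zero distance at zero noise", {
  ne <- noise_experiment(0, reps = 5, seed = 1)
  expect_equal(ne$mean_distance, 0)
  expect_equal(ne$sd_distance, 0)
})

test_that("mean DTW distance grows linearly with the noise level", {
  ne <- noise_experiment(seq(0.05, 0.5, by = 0.05), reps = 200, seed = 2)
  expect_true(all(diff(ne$mean_distance) > 0))
  expect_gte(stats::cor(ne$sigma, ne$mean_distance), 0.99)
})

test_that("configuration validation rejects nonsense", {
  expect_error(sim_config(n_gestures = 0))
  expect_error(sim_config(noise_sigma = -1))
  expect_error(sim_config(time_jitter = 1))
})
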