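test_that("powergrip factors average the center third over time and recordings", {
  rec <- matrix(4, 2, 9)
  f <- powergrip_factors(list(rec))
  expect_equal(unname(f$per_sensor), c(4, 4))
  expect_equal(f$batch, 4)
  # two recordings with middle-third channel means 2 and 6 average to 4
  r1 <- matrix(2, 1, 9); r2 <- matrix(6, 1, 9)
  expect_equal(unname(powergrip_factors(list(r1, r2))$per_sensor), 4)
  # batch factor is the mean over sensors
  rec2 <- rbind(rep(2, 9), rep(6, 9))
  expect_equal(powergrip_factors(list(rec2))$batch, 4)
})

test_that("only the center third contributes (half-open index convention)", {
  # L = 10: frames 4..6 are the middle third under [floor(L/3), floor(2L/3))
  rec <- matrix(0, 1, 10)
  rec[1, 4:6] <- 5
  expect_equal(unname(powergrip_factors(list(rec))$per_sensor), 5)
  expect_error(powergrip_factors(list(matrix(1, 1, 2))), "at least 3")
  expect_error(powergrip_factors(list(matrix(0, 1, 9))), "non-positive")
})

test_that("batch and sensor normalization rescale as defined", {
  f <- structure(list(per_sensor = c(2, 6), batch = 4),
                 class = "normalization_factors")
  s <- rbind(c(2, 2), c(6, 6))
  expect_equal(batch_normalize(s, f), s / 4)
  expect_equal(sensor_normalize(s, f), rbind(c(1, 1), c(1, 1)))
  unit <- structure(list(per_sensor = c(1, 1), batch = 1),
                    class = "normalization_factors")
  expect_equal(batch_normalize(s, unit), s)
  expect_equal(sensor_normalize(s, unit), s)
})

test_that("equal per-sensor factors make the two schemes coincide", {
  f <- structure(list(per_sensor = c(3, 3), batch = 3),
                 class = "normalization_factors")
  set.seed(2)
  s <- matrix(rnorm(20), 2)
  expect_equal(sensor_normalize(s, f), batch_normalize(s, f))
})

test_that("batch normalization scales DTW distances by exactly 1/batch", {
  set.seed(4)
  X <- random_series(12, 3, integer = FALSE)
  Y <- random_series(15, 3, integer = FALSE)
  f <- structure(list(per_sensor = rep(2.5, 3), batch = 2.5),
                 class = "normalization_factors")
  expect_equal(normalized_dtw(batch_normalize(X, f), batch_normalize(Y, f)),
               normalized_dtw(X, Y) / 2.5, tolerance = 1e-12)
})

test_that("a dataset compared with its copy has matching distributions", {
  sim <- small_multiday(seed = 30, samples = 5, gestures = 2, seatings = 1)
  out <- interparticipant_distributions(sim$dataset, sim$dataset)
  for (g in names(out)) {
    expect_equal(out[[g]]$delta_A, out[[g]]$delta_B)
    # cross distribution includes the self-pair zeros
    expect_equal(sum(out[[g]]$Delta_AB == 0), 5L)
  }
})

test_that("gestures present in only one dataset are skipped with a warning", {
  simA <- small_multiday(seed = 30, samples = 4, gestures = 3, seatings = 1)
  simB <- small_multiday(seed = 30, samples = 4, gestures = 2, seatings = 1)
  expect_warning(out <- interparticipant_distributions(simA$dataset,
                                                       simB$dataset),
                 "g03")
  expect_setequal(names(out), c("g01", "g02"))
})

test_that("batch normalization recovers twin subjects differing by pure gain", {
  cfgA <- sim_config(n_gestures = 3, samples_per_gesture = 8,
                     length_range = c(30L, 45L), subject_scale = 1,
                     subject = "A", seed = 33)
  cfgB <- sim_config(n_gestures = 3, samples_per_gesture = 8,
                     length_range = c(30L, 45L), subject_scale = 3,
                     subject = "B", seed = 34, template_seed = 33)
  simA <- simulate_dataset(cfgA); simB <- simulate_dataset(cfgB)
  fA <- powergrip_factors(simA$powergrips)
  fB <- powergrip_factors(simB$powergrips)
  expect_equal(fB$batch / fA$batch, 3, tolerance = 0.05)

  raw <- interparticipant_distributions(simA$dataset, simB$dataset, "none")
  norm <- interparticipant_distributions(simA$dataset, simB$dataset, "batch",
                                         factorsA = fA, factorsB = fB)
  for (g in names(norm)) {
    d <- norm[[g]]
    delta <- c(d$delta_A, d$delta_B)
    expect_lt(abs(median(d$Delta_AB) - median(delta)),
              0.1 * dist_percentile(delta, 90))
    # without normalization the amplitude gap dominates the cross distances
    expect_gt(median(raw[[g]]$Delta_AB), median(c(raw[[g]]$delta_A,
                                                  raw[[g]]$delta_B)))
  }
})

test_that("normalization requires each subject's factors and positive values", {
  sim <- small_multiday(seed = 30, samples = 4, gestures = 2, seatings = 1)
  expect_error(interparticipant_distributions(sim$dataset, sim$dataset,
                                              "batch"),
               "factors")
  bad <- structure(list(per_sensor = c(0, 1), batch = 0.5),
                   class = "normalization_factors")
  expect_error(sensor_normalize(matrix(1, 2, 3), bad), "positive")
})
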