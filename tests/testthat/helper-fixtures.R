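# Fixture builders shared across test files. Everything is generated in
# code; seeds are fixed so tests are reproducible.

# A single-frame, single-channel series: DTW distance between two of these
# is |a - b| (raw) or |a - b| / sqrt(2) (normalized).
pt <- function(v) matrix(v, nrow = 1)

# Random multichannel series with integer or real values.
random_series <- function(len, channels = 2L, integer = TRUE) {
  vals <- if (integer) sample(0:9, channels * len, replace = TRUE)
  else stats::rnorm(channels * len)
  matrix(as.double(vals), nrow = channels)
}

# A tight cluster of single-frame samples around a center value.
point_cluster <- function(center, n = 5, spread = 0.01) {
  lapply(seq_len(n), function(i) pt(center + spread * (i - (n + 1) / 2)))
}

# Small well-separated multiday-style simulation used by several files.
small_multiday <- function(seed = 3L, samples = 8L, gestures = 3L,
                           seatings = 2L, noise = 0.05) {
  simulate_dataset(sim_config(
    n_gestures = gestures, samples_per_gesture = samples,
    n_seatings = seatings, length_range = c(30L, 45L),
    noise_sigma = noise, seed = seed))
}

expect_metrics_identity <- function(m, tol = 1e-12) {
  if (m$n_accepted > 0)
    expect_lt(abs(m$alpha - m$beta * (1 - m$gamma)), tol)
  expect_true(m$alpha >= 0 && m$alpha <= 1)
  expect_true(m$gamma >= 0 && m$gamma <= 1)
}
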