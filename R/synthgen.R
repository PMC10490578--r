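#' Synthetic sEMG simulation settings
#'
#' Configuration for the synthetic gesture generator. The generator
#' emulates the structure of armband sEMG study data: per-gesture smooth
#' channel-activation envelopes, sample-to-sample variation in length and
#' amplitude, additive sensor noise, a persistent fractional rotation of
#' the channel ring per seating (the armband is never re-seated in exactly
#' the same position), and a global per-subject gain.
#'
#' Defaults mirror the study layout: 7 gestures, 8 channels at 200 Hz,
#' 100 samples per gesture for a single-seating dataset (use
#' `n_seatings = 5, samples_per_gesture = 20` for the multi-seating
#' layout). Gesture lengths of 80-120 frames correspond to 0.4-0.6 s
#' hand gestures.
#'
#' @param n_gestures number of gesture classes.
#' @param samples_per_gesture samples per gesture *per seating*.
#' @param n_seatings number of armband seatings (recording days).
#' @param channels sensor count (default 8).
#' @param length_range frame-count range for the nominal gesture length.
#' @param noise_sigma standard deviation of the additive zero-mean
#'   Gaussian sensor noise, in sensor intensity units (envelope peaks are
#'   of order 1).
#' @param amplitude_jitter fractional per-sample amplitude variation.
#' @param time_jitter fractional per-sample duration variation (samples of
#'   one gesture differ in length when > 0).
#' @param seating_rotation maximum fractional channel-ring rotation per
#'   re-seating, in sensor positions (seating 1 is the reference, offset 0).
#' @param subject_scale global gain of this subject's recordings; applied
#'   to the complete signal, so two subjects simulated from the same seed
#'   differ only by this amplitude factor.
#' @param subject subject id stored in the dataset.
#' @param n_powergrips,powergrip_length,mvc_level maximum-voluntary-
#'   contraction recordings: how many, their length in frames, and the
#'   plateau level relative to the unit gesture-envelope amplitude.
#' @param seed RNG seed; every generator operation is deterministic
#'   under it.
#' @param template_seed seed for the gesture templates only (defaults to
#'   `seed`). Give two subject configurations the same `template_seed` but
#'   different `seed`s to share a gesture vocabulary while drawing
#'   independent noise — e.g. twin subjects differing only in gain.
#' @return a list of class `"sim_config"`.
#' @export
sim_config <- function(n_gestures = 7L, samples_per_gesture = 100L,
                       n_seatings = 1L, channels = 8L,
                       length_range = c(80L, 120L), noise_sigma = 0.05,
                       amplitude_jitter = 0.1, time_jitter = 0.15,
                       seating_rotation = 0.5, subject_scale = 1,
                       subject = "s1", n_powergrips = 3L,
                       powergrip_length = 300L, mvc_level = 2,
                       seed = 1L, template_seed = seed) {
  cfg <- list(n_gestures = as.integer(n_gestures),
              samples_per_gesture = as.integer(samples_per_gesture),
              n_seatings = as.integer(n_seatings),
              channels = as.integer(channels),
              length_range = as.integer(length_range),
              noise_sigma = noise_sigma,
              amplitude_jitter = amplitude_jitter,
              time_jitter = time_jitter,
              seating_rotation = seating_rotation,
              subject_scale = subject_scale,
              subject = subject,
              n_powergrips = as.integer(n_powergrips),
              powergrip_length = as.integer(powergrip_length),
              mvc_level = mvc_level,
              seed = as.integer(seed),
              template_seed = as.integer(template_seed))
  with(cfg, {
    stopifnot(n_gestures >= 1L, samples_per_gesture >= 1L, n_seatings >= 1L,
              channels >= 1L, length(length_range) == 2L,
              all(length_range >= 2L), noise_sigma >= 0,
              amplitude_jitter >= 0, amplitude_jitter < 1,
              time_jitter >= 0, time_jitter < 1, seating_rotation >= 0,
              subject_scale > 0, n_powergrips >= 1L, powergrip_length >= 3L,
              mvc_level > 0)
  })
  structure(cfg, class = "sim_config")
}

# Run code under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Gesture templates: smooth multichannel activation envelopes
#'
#' A gesture template is a smooth non-negative channels x frames envelope,
#' built per channel as a sum of 1-3 randomized Gaussian bumps (random
#' center, width, height). Templates are a deterministic function of the
#' configuration seed and the gesture index, so two subjects simulated
#' from the same seed share their gesture vocabulary.
#'
#' @param label_index gesture index (1-based).
#' @param config a [sim_config()].
#' @return series matrix with attribute `"label"`.
#' @export
make_template <- function(label_index, config) {
  stopifnot(inherits(config, "sim_config"))
  L0 <- round(mean(config$length_range))
  seed <- (config$template_seed %% 100000L) * 10007L + label_index * 101L
  env <- with_seed(seed, {
    t <- seq_len(L0)
    m <- matrix(0, config$channels, L0)
    for (c in seq_len(config$channels)) {
      for (b in seq_len(sample(1:3, 1))) {
        h <- stats::runif(1, 0.2, 1)
        ctr <- stats::runif(1, 0.15, 0.85) * L0
        w <- stats::runif(1, 0.05, 0.15) * L0
        m[c, ] <- m[c, ] + h * exp(-((t - ctr)^2) / (2 * w^2))
      }
    }
    m
  })
  structure(env, label = sprintf("g%02d", label_index))
}

# Linear-interpolation resampling of every channel to a new length.
resample_series <- function(x, new_len) {
  if (new_len == ncol(x)) return(x)
  old <- seq(0, 1, length.out = ncol(x))
  pos <- seq(0, 1, length.out = new_len)
  t(apply(x, 1, function(row) stats::approx(old, row, xout = pos)$y))
}

# Fractional circular rotation of the channel ring: each output channel is
# interpolated between the two adjacent input sensors.
rotate_channels <- function(x, offset) {
  if (offset == 0) return(x)
  C <- nrow(x)
  k <- floor(offset); f <- offset - k
  i1 <- ((seq_len(C) - 1 + k) %% C) + 1
  i2 <- ((seq_len(C) + k) %% C) + 1
  (1 - f) * x[i1, , drop = FALSE] + f * x[i2, , drop = FALSE]
}

#' Draw one synthetic gesture sample
#'
#' Time-rescales the template by a random factor (so sample lengths vary),
#' scales the amplitude within the configured jitter, adds i.i.d. zero-mean
#' Gaussian sensor noise per channel and frame, and applies the subject
#' gain to the complete signal. Consumes the current RNG stream; seed it
#' (or use [simulate_dataset()]) for reproducibility.
#'
#' @param template a [make_template()] envelope.
#' @param config a [sim_config()].
#' @return a series matrix.
#' @export
sample_gesture <- function(template, config) {
  stopifnot(inherits(config, "sim_config"))
  tj <- config$time_jitter
  u <- if (tj > 0) stats::runif(1, 1 - tj, 1 + tj) else 1
  L <- max(2L, round(ncol(template) * u))
  warped <- resample_series(unclass(template), L)
  aj <- config$amplitude_jitter
  amp <- if (aj > 0) stats::runif(1, 1 - aj, 1 + aj) else 1
  noise <- if (config$noise_sigma > 0)
    matrix(stats::rnorm(length(warped), 0, config$noise_sigma),
           nrow(warped), ncol(warped))
  else 0
  config$subject_scale * (amp * warped + noise)
}

#' Simulate a full labeled gesture dataset
#'
#' Generates, per seating and gesture, the configured number of samples.
#' Each seating beyond the first applies a persistent random fractional
#' rotation of the channel ring to all its samples, emulating armband
#' re-seating. Powergrip (maximum-voluntary-contraction) recordings are
#' generated as near-saturation plateaus with ramp-up and ramp-down
#' thirds, at a per-channel level drawn once per subject. Fully
#' deterministic under the configuration seed.
#'
#' @param config a [sim_config()].
#' @return list with `dataset` (a [gesture_dataset()]), `templates`,
#'   `powergrips` (list of series), `seating_offsets`, and `config`.
#' @examples
#' sim <- simulate_dataset(sim_config(n_gestures = 2,
#'                                    samples_per_gesture = 3, seed = 7))
#' sim$dataset
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  templates <- lapply(seq_len(config$n_gestures), make_template,
                      config = config)
  # the per-channel MVC profile is part of the subject's physiology: like
  # the templates it derives from template_seed, so twin-subject setups
  # (same template_seed, different seed) share it
  mvc <- with_seed((config$template_seed %% 100000L) * 10007L + 99990L,
                   config$mvc_level * stats::runif(config$channels, 0.8, 1.2))
  with_seed(config$seed, {
    offsets <- c(0, if (config$n_seatings > 1L)
      stats::runif(config$n_seatings - 1L, 0, config$seating_rotation))
    samples <- list(); label <- character(0); seating <- integer(0)
    for (s in seq_len(config$n_seatings)) {
      for (tpl in templates) {
        for (r in seq_len(config$samples_per_gesture)) {
          smp <- sample_gesture(tpl, config)
          samples[[length(samples) + 1L]] <- rotate_channels(smp, offsets[s])
          label <- c(label, attr(tpl, "label"))
          seating <- c(seating, s)
        }
      }
    }
    powergrips <- lapply(seq_len(config$n_powergrips), function(i) {
      L <- config$powergrip_length
      third <- floor(L / 3)
      profile <- c(seq(0, 1, length.out = third),
                   rep(1, L - 2L * third),
                   seq(1, 0, length.out = third))
      sig <- outer(mvc, profile)
      noise <- matrix(stats::rnorm(length(sig), 0, config$noise_sigma),
                      nrow(sig), ncol(sig))
      config$subject_scale * (sig + noise)
    })
    list(dataset = gesture_dataset(samples, label,
                                   subject = config$subject,
                                   seating = seating),
         templates = templates, powergrips = powergrips,
         seating_offsets = offsets, config = config)
  })
}

#' Base curve for the noise-vs-distance experiment
#'
#' A single smooth Gaussian bump of unit height centered at `mu` with
#' width `kappa` on a fixed grid — the noise-free signal the experiment
#' perturbs.
#'
#' @param length grid length in frames.
#' @param mu bump center, `kappa` bump width, `t_max` grid end (grid runs
#'   0 to `t_max`).
#' @return a 1 x length series matrix.
#' @export
noise_base_curve <- function(length = 128L, mu = 5, kappa = 2, t_max = 10) {
  t <- seq(0, t_max, length.out = length)
  matrix(exp(-((t - mu)^2) / (2 * kappa^2)), nrow = 1)
}

#' DTW distance as a function of noise level
#'
#' Adds two independently drawn zero-mean Gaussian noise patterns to the
#' same base curve — two recordings of the identical signal, differing only
#' in noise — and computes their DTW distance, repeatedly per noise level.
#' Although the noise-free distance is exactly zero, noise inflates the
#' distance roughly linearly in sigma, which is why distance distributions
#' wash out at low signal-to-noise ratios.
#'
#' @param sigmas vector of noise standard deviations.
#' @param reps repetitions per noise level (>= 2).
#' @param base_curve the clean signal (default [noise_base_curve()]).
#' @inheritParams dtw_align
#' @param normalize length-normalize the distances? Default `FALSE` (raw
#'   accumulated cost of the single-channel comparison).
#' @param seed optional seed for reproducibility.
#' @return data frame with columns `sigma`, `mean_distance`, `sd_distance`.
#' @export
noise_experiment <- function(sigmas, reps = 1000L, base_curve = NULL,
                             cost = "euclidean", normalize = FALSE,
                             seed = NULL) {
  if (reps < 2L) stop("reps must be >= 2")
  if (any(sigmas < 0)) stop("sigmas must be >= 0")
  if (is.null(base_curve)) base_curve <- noise_base_curve()
  base_curve <- mc_series(base_curve)
  if (!is.null(seed)) set.seed(seed)
  L <- length(base_curve)
  rows <- lapply(sigmas, function(s) {
    d <- vapply(seq_len(reps), function(r) {
      X <- base_curve + stats::rnorm(L, 0, s)
      Y <- base_curve + stats::rnorm(L, 0, s)
      dtw_distance(X, Y, cost = cost, normalize = normalize)
    }, numeric(1))
    data.frame(sigma = s, mean_distance = mean(d), sd_distance = stats::sd(d))
  })
  do.call(rbind, rows)
}
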