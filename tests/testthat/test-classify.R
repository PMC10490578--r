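test_that("a query identical to a reference gets its label at distance 0", {
  sim <- small_multiday(seed = 4, samples = 4, gestures = 3, seatings = 1)
  refs <- build_reference_set(sim$dataset, "uncondensed")
  out <- knn_classify(sim$dataset$samples[[1]], refs)
  expect_equal(out$predicted, sim$dataset$info$label[1])
  expect_equal(out$nearest_distance, 0)
  expect_false(out$rejected)
})

test_that("condensed reference sets hold one entry per label and force k = 1", {
  sim <- small_multiday(seed = 4, samples = 4, gestures = 3, seatings = 1)
  for (mode in c("rep", "dba")) {
    refs <- build_reference_set(sim$dataset, mode)
    expect_length(refs$series, 3L)
    expect_setequal(refs$labels, dataset_labels(sim$dataset))
    expect_error(knn_classify(sim$dataset$samples[[1]], refs, k = 2),
                 "k = 1")
  }
  refs <- build_reference_set(sim$dataset, "uncondensed")
  expect_error(knn_classify(sim$dataset$samples[[1]], refs, k = 99),
               "exceeds")
})

test_that("cutoff policy accepts near and rejects far queries", {
  refs <- build_reference_set(
    gesture_dataset(c(point_cluster(0), point_cluster(10)),
                    rep(c("a", "b"), each = 5)), "uncondensed")
  near <- classify_with_cutoff(pt(0.001), refs, c(a = 1, b = 1))
  expect_false(near$rejected)
  expect_equal(near$predicted, "a")
  far <- classify_with_cutoff(pt(4.9), refs, c(a = 1, b = 1))
  expect_true(far$rejected)
  expect_true(is.na(far$predicted))
  # zero cutoffs reject anything not identical to a reference
  zero <- classify_with_cutoff(pt(0.001), refs, c(a = 0, b = 0))
  expect_true(zero$rejected)
  expect_error(classify_with_cutoff(pt(0), refs, c(a = 1)), "missing")
})

test_that("noise-only queries are rejected at tight percentile cutoffs", {
  sim <- small_multiday(seed = 14, samples = 8, gestures = 3, seatings = 1)
  refs <- build_reference_set(sim$dataset, "uncondensed")
  cut <- cutoffs_from_percentile(refs, 40)
  set.seed(99)
  noise_query <- matrix(rnorm(8 * 35, sd = 0.05), nrow = 8)
  out <- classify_with_cutoff(noise_query, refs, cut)
  expect_true(out$rejected)
})

test_that("acceptance metrics follow the defining arithmetic", {
  m <- acceptance_metrics(n_correct = 7, n_accepted = 8, n_total = 10)
  expect_equal(m$alpha, 0.7)
  expect_equal(m$beta, 0.875)
  expect_equal(m$gamma, 0.2)
  expect_metrics_identity(m)
  all_rej <- acceptance_metrics(0, 0, 5)
  expect_equal(all_rej$gamma, 1)
  expect_equal(all_rej$alpha, 0)
  expect_true(is.na(all_rej$beta))
})

test_that("without a cutoff nothing is rejected and alpha equals beta", {
  sim <- small_multiday(seed = 6, samples = 6, gestures = 3, seatings = 1)
  splits <- make_splits(sim$dataset,
                        split_plan("random_fraction", repeats = 1, seed = 2))
  refs <- build_reference_set(splits[[1]]$reference, "uncondensed")
  m <- evaluate_classifier(splits[[1]]$test, refs)
  expect_equal(m$gamma, 0)
  expect_equal(m$alpha, m$beta)
  expect_metrics_identity(m)
})

test_that("percentile cutoffs hit the distribution's extremes", {
  delta <- c(0, 10)
  expect_equal(cutoff_from_percentile(delta, 100), 10)
  expect_equal(cutoff_from_percentile(delta, 50), 5)
  expect_equal(cutoff_from_percentile(delta, 0), 0)
})

test_that("random-fraction splits are stratified, disjoint and seeded", {
  sim <- small_multiday(seed = 10, samples = 10, gestures = 3, seatings = 1)
  plan <- split_plan("random_fraction", fraction = 0.7, repeats = 3, seed = 5)
  splits <- make_splits(sim$dataset, plan)
  expect_length(splits, 3L)
  for (sp in splits) {
    expect_equal(as.vector(table(sp$reference$info$label)), rep(7L, 3))
    expect_equal(as.vector(table(sp$test$info$label)), rep(3L, 3))
    expect_equal(n_samples(sp$reference) + n_samples(sp$test),
                 n_samples(sim$dataset))
  }
  again <- make_splits(sim$dataset, plan)
  expect_identical(splits[[2]]$reference$info, again[[2]]$reference$info)
})

test_that("leave-days-out splits hold complete seatings out", {
  sim <- small_multiday(seed = 10, samples = 4, gestures = 3, seatings = 3)
  plan <- split_plan("leave_days_out", test_days = list(2L))
  sp <- make_splits(sim$dataset, plan)[[1]]
  expect_setequal(unique(sp$reference$info$seating), c(1L, 3L))
  expect_equal(unique(sp$test$info$seating), 2L)
  # without test_days, each seating is held out once
  all_sp <- make_splits(sim$dataset, split_plan("leave_days_out"))
  expect_length(all_sp, 3L)
  expect_error(make_splits(sim$dataset,
                           split_plan("leave_days_out",
                                      test_days = list(9L))),
               "unknown seating")
})

test_that("per-day subsampling keeps s samples per gesture and day", {
  sim <- small_multiday(seed = 10, samples = 5, gestures = 3, seatings = 4)
  sub <- subsample_reference_per_day(sim$dataset, 3, seed = 1)
  expect_equal(as.vector(table(sub$info$label)), rep(12L, 3)) # 3 per day x 4 days
  full <- subsample_reference_per_day(sim$dataset, 5, seed = 1)
  expect_equal(n_samples(full), n_samples(sim$dataset))
  one <- subsample_reference_per_day(sim$dataset, 1, seed = 1)
  expect_equal(as.vector(table(one$info$label)), rep(4L, 3))
  expect_error(subsample_reference_per_day(sim$dataset, 6), "cannot keep")
})

test_that("rejection rate falls as the cutoff percentile grows, all modes", {
  sim <- small_multiday(seed = 16, samples = 8, gestures = 3, seatings = 2)
  plan <- split_plan("random_fraction", repeats = 2, seed = 4)
  sw <- sweep_cutoffs(sim$dataset, plan, percentiles = c(0, 25, 50, 75, 100))
  for (mode in unique(sw$mode)) {
    g <- sw$gamma_mean[sw$mode == mode]
    expect_true(all(diff(g) <= 1e-12))
    # tightest cutoff rejects the most, widest covers the whole cluster
    expect_equal(max(g), g[1])
  }
  wide <- sw[sw$percentile == 100 & sw$mode == "uncondensed", ]
  expect_lt(wide$gamma_mean, 0.05)
})

test_that("condensed modes reject at least as much as uncondensed on merged splits", {
  sim <- small_multiday(seed = 16, samples = 10, gestures = 3, seatings = 2)
  plan <- split_plan("random_fraction", repeats = 2, seed = 8)
  sw <- sweep_cutoffs(sim$dataset, plan, percentiles = c(5, 20, 40, 60, 80))
  for (p in unique(sw$percentile)) {
    g <- function(m) sw$gamma_mean[sw$mode == m & sw$percentile == p]
    expect_gte(g("rep") + 1e-12, g("uncondensed"))
    expect_gte(g("dba") + 1e-12, g("uncondensed"))
  }
})

test_that("well-separated clusters classify perfectly in all three modes", {
  sim <- small_multiday(seed = 25, samples = 8, gestures = 3, seatings = 2,
                        noise = 0.03)
  rep <- separability_report(sim$dataset)
  expect_true(all(rep$margin > 0))
  plans <- list(split_plan("random_fraction", repeats = 1, seed = 3),
                split_plan("leave_days_out", test_days = list(2L)))
  for (plan in plans) for (mode in c("uncondensed", "rep", "dba")) {
    sp <- make_splits(sim$dataset, plan)[[1]]
    refs <- build_reference_set(sp$reference, mode)
    m <- evaluate_classifier(sp$test, refs)
    expect_equal(m$alpha, 1)
  }
})

test_that("cutoffs can alternatively come from member-to-reference distances", {
  sim <- small_multiday(seed = 24, samples = 6, gestures = 3, seatings = 1)
  refs <- build_reference_set(sim$dataset, "rep", cutoff_source = "to_reference")
  # one distance per member, including the reference itself (distance 0)
  expect_true(all(vapply(refs$delta, length, integer(1)) == 6L))
  expect_true(all(vapply(refs$delta, min, numeric(1)) == 0))
})
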