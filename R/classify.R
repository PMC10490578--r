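#' Build a reference set for nearest-neighbor classification
#'
#' A reference set holds the labeled series a query is compared against,
#' in one of three modes: `"uncondensed"` keeps every reference sample,
#' `"rep"` keeps one representative per gesture, `"dba"` one barycenter per
#' gesture (see [condense_dataset()]). Alongside the series it retains, per
#' gesture, the intracluster distance distribution delta_k of the reference
#' samples, from which percentile-based acceptance cutoffs are derived.
#'
#' @param dataset a [gesture_dataset()] of reference samples.
#' @param mode `"uncondensed"`, `"rep"` or `"dba"`.
#' @inheritParams dtw_align
#' @param normalize use length-normalized DTW throughout (default)?
#' @param max_iter,tol DBA settings, see [dba_barycenter()].
#' @param cutoff_source `"pairwise"` (default) derives delta_k from the
#'   pairwise distances among the reference samples of gesture k, before
#'   any condensation — the same distribution for all three modes;
#'   `"to_reference"` instead uses the distances of the members to the
#'   condensed reference (condensed modes only).
#' @param cluster_distmats optional named list of precomputed pairwise
#'   distance matrices per cluster (reused across modes by [sweep_cutoffs()]).
#' @return object of class `"reference_set"`: list with `mode`, `series`,
#'   `labels`, `delta` (named list of numeric), `cost`, `normalize`.
#' @export
build_reference_set <- function(dataset,
                                mode = c("uncondensed", "rep", "dba"),
                                cost = "euclidean", normalize = TRUE,
                                max_iter = 30L, tol = 1e-6,
                                cutoff_source = c("pairwise", "to_reference"),
                                cluster_distmats = NULL) {
  mode <- match.arg(mode)
  cutoff_source <- match.arg(cutoff_source)
  cls <- clusters(dataset)
  labs <- names(cls)
  if (is.null(cluster_distmats))
    cluster_distmats <- lapply(cls, function(cl)
      if (length(cl) >= 2L)
        dtw_distance_matrix(cl, cost = cost, normalize = normalize)
      else matrix(0, 1, 1))
  delta <- lapply(cluster_distmats, function(D) D[upper.tri(D)])
  if (mode == "uncondensed") {
    series <- unlist(cls, recursive = FALSE, use.names = FALSE)
    labels <- rep(labs, vapply(cls, length, integer(1)))
  } else {
    series <- vector("list", length(cls))
    for (i in seq_along(cls)) {
      rep_i <- select_representative(cls[[i]], distmat = cluster_distmats[[i]])
      series[[i]] <- if (mode == "rep") rep_i$series
        else dba_barycenter(cls[[i]], rep_i$series, max_iter = max_iter,
                            tol = tol)
    }
    labels <- labs
    if (cutoff_source == "to_reference")
      delta <- lapply(seq_along(cls), function(i)
        as.vector(dtw_distance_matrix(cls[[i]], series[i], cost = cost,
                                      normalize = normalize)))
  }
  names(delta) <- labs
  structure(list(mode = mode, series = series, labels = labels,
                 delta = delta, cost = cost, normalize = normalize),
            class = "reference_set")
}

#' @export
print.reference_set <- function(x, ...) {
  cat("Reference set (", x$mode, "): ", length(x$series), " series, ",
      length(unique(x$labels)), " gestures\n", sep = "")
  invisible(x)
}

#' k-nearest-neighbor classification under DTW
#'
#' Classifies one query series against a reference set by the majority
#' label among its k nearest references under normalized DTW. With
#' condensed references only k = 1 is meaningful (one entry per gesture)
#' and larger k is refused. Voting ties are broken by the smaller summed
#' distance of the tied labels, then by label order.
#'
#' @param query a series matrix.
#' @param refs a [build_reference_set()] object.
#' @param k number of neighbors (default 1).
#' @return list with `predicted`, `nearest_label`, `nearest_distance`,
#'   and `rejected` (always `FALSE` here; see [classify_with_cutoff()]).
#' @export
knn_classify <- function(query, refs, k = 1L) {
  d <- ref_distances(query, refs)
  classify_from_distances(d, refs, k, cutoffs = NULL)
}

#' Classification with a distance-cutoff acceptance policy
#'
#' As [knn_classify()] with k = 1, but the sample must be closer than the
#' cutoff distance of the gesture it would be assigned to; otherwise it is
#' rejected rather than classified. This is what lets the classifier
#' ignore background motion and gestures outside the trained set.
#'
#' @inheritParams knn_classify
#' @param cutoffs named numeric vector of per-gesture cutoff distances
#'   (must cover every label in `refs`), e.g. from
#'   [cutoff_from_percentile()].
#' @return as [knn_classify()]; `predicted` is `NA` and `rejected` is
#'   `TRUE` when the nearest distance exceeds the cutoff.
#' @export
classify_with_cutoff <- function(query, refs, cutoffs) {
  check_cutoffs(cutoffs, refs)
  d <- ref_distances(query, refs)
  classify_from_distances(d, refs, 1L, cutoffs)
}

ref_distances <- function(query, refs) {
  as.vector(dtw_distance_matrix(list(query), refs$series, cost = refs$cost,
                                normalize = refs$normalize))
}

check_cutoffs <- function(cutoffs, refs) {
  missing <- setdiff(unique(refs$labels), names(cutoffs))
  if (length(missing))
    stop("cutoffs missing for label(s): ", paste(missing, collapse = ", "))
  invisible(TRUE)
}

classify_from_distances <- function(d, refs, k, cutoffs) {
  n <- length(d)
  if (k < 1L) stop("k must be >= 1")
  if (k > n) stop("k exceeds the number of references (", n, ")")
  if (k > 1L && refs$mode != "uncondensed")
    stop("condensed reference sets require k = 1")
  ord <- order(d)
  nearest <- ord[1L]
  nearest_label <- refs$labels[nearest]
  nearest_distance <- d[nearest]
  predicted <- if (k == 1L) nearest_label else {
    nn <- ord[seq_len(k)]
    votes <- table(refs$labels[nn])
    top <- names(votes)[votes == max(votes)]
    if (length(top) > 1L) {
      sums <- vapply(top, function(l) sum(d[nn][refs$labels[nn] == l]),
                     numeric(1))
      top <- sort(top[sums == min(sums)])
    }
    top[1L]
  }
  rejected <- FALSE
  if (!is.null(cutoffs) && nearest_distance > cutoffs[[nearest_label]]) {
    rejected <- TRUE
    predicted <- NA_character_
  }
  list(predicted = predicted, nearest_label = nearest_label,
       nearest_distance = nearest_distance, rejected = rejected)
}

#' Percentile-based acceptance cutoffs
#'
#' The cutoff distance for a gesture is a percentile of its intracluster
#' distance distribution delta_k: the 100th percentile includes the
#' furthest outlier of the reference cluster, smaller percentiles tighten
#' acceptance. `cutoffs_from_percentile()` derives the full named vector
#' for a reference set.
#'
#' @param delta numeric vector, the intracluster distances of one gesture.
#' @param p percent in \[0, 100\].
#' @return a single cutoff distance; for `cutoffs_from_percentile()` a
#'   named vector over the reference set's labels.
#' @export
cutoff_from_percentile <- function(delta, p) dist_percentile(delta, p)

#' @rdname cutoff_from_percentile
#' @param refs a [build_reference_set()] object.
#' @export
cutoffs_from_percentile <- function(refs, p) {
  vapply(refs$delta, dist_percentile, numeric(1), p = p)
}

#' Acceptance metrics: total accuracy, classification accuracy, rejection
#'
#' For a batch of classified test samples under a cutoff policy: the total
#' accuracy alpha is the fraction of all samples classified correctly; the
#' classification accuracy beta is the fraction correct among the samples
#' accepted for classification; the rejection rate gamma is the fraction
#' rejected. The identity `alpha = beta * (1 - gamma)` holds whenever
#' anything is accepted; beta is `NA` when everything is rejected.
#'
#' @param test a [gesture_dataset()] of labeled test samples.
#' @param refs a [build_reference_set()] object.
#' @param cutoffs optional named per-gesture cutoff vector; without it no
#'   sample is rejected and alpha equals beta.
#' @param k neighbors for the uncondensed mode (default 1).
#' @return object of class `"acceptance_metrics"`: list with `alpha`,
#'   `beta`, `gamma`, `n_total`, `n_accepted`, `n_correct`.
#' @export
evaluate_classifier <- function(test, refs, cutoffs = NULL, k = 1L) {
  res <- classify_dataset(test, refs, cutoffs = cutoffs, k = k)
  acceptance_metrics(n_correct = sum(res$correct),
                     n_accepted = sum(!res$rejected),
                     n_total = nrow(res))
}

#' @rdname evaluate_classifier
#' @return `classify_dataset()` returns a data frame with one row per test
#'   sample: `truth`, `predicted`, `nearest_label`, `nearest_distance`,
#'   `rejected`, `correct`.
#' @export
classify_dataset <- function(test, refs, cutoffs = NULL, k = 1L) {
  if (!is.null(cutoffs)) check_cutoffs(cutoffs, refs)
  D <- dtw_distance_matrix(test$samples, refs$series, cost = refs$cost,
                           normalize = refs$normalize)
  out <- vector("list", nrow(D))
  for (i in seq_len(nrow(D)))
    out[[i]] <- classify_from_distances(D[i, ], refs, k, cutoffs)
  df <- data.frame(
    truth = test$info$label,
    predicted = vapply(out, `[[`, character(1), "predicted"),
    nearest_label = vapply(out, `[[`, character(1), "nearest_label"),
    nearest_distance = vapply(out, `[[`, numeric(1), "nearest_distance"),
    rejected = vapply(out, `[[`, logical(1), "rejected"),
    stringsAsFactors = FALSE)
  df$correct <- !df$rejected & !is.na(df$predicted) & df$predicted == df$truth
  df
}

#' @rdname evaluate_classifier
#' @param n_correct,n_accepted,n_total raw counts.
#' @export
acceptance_metrics <- function(n_correct, n_accepted, n_total) {
  if (n_total < 1L) stop("metrics need at least one test sample")
  structure(list(
    alpha = n_correct / n_total,
    beta = if (n_accepted > 0) n_correct / n_accepted else NA_real_,
    gamma = (n_total - n_accepted) / n_total,
    n_total = n_total, n_accepted = n_accepted, n_correct = n_correct),
    class = "acceptance_metrics")
}

#' @export
print.acceptance_metrics <- function(x, ...) {
  cat(sprintf(
    "alpha (total acc.) %.4f | beta (classif. acc.) %s | gamma (rejection) %.4f  [%d/%d accepted]\n",
    x$alpha, ifelse(is.na(x$beta), "NA", sprintf("%.4f", x$beta)), x$gamma,
    x$n_accepted, x$n_total))
  invisible(x)
}

#' Reference/test split plans
#'
#' Two strategies mirror the study designs: `"random_fraction"` splits each
#' gesture cluster at random into a reference fraction and a test rest
#' (stratified, repeated), and `"leave_days_out"` holds complete seatings
#' (recording days) out as the test set, representing a freshly re-seated
#' armband.
#'
#' @param strategy `"random_fraction"` or `"leave_days_out"`.
#' @param fraction reference fraction per gesture (default 0.7).
#' @param repeats number of random splits (default 10).
#' @param seed RNG seed making the splits reproducible.
#' @param test_days for `"leave_days_out"`: list of seating-id vectors,
#'   one element per split; `NULL` holds each seating out once in turn.
#' @return object of class `"split_plan"`.
#' @export
split_plan <- function(strategy = c("random_fraction", "leave_days_out"),
                       fraction = 0.7, repeats = 10L, seed = 1L,
                       test_days = NULL) {
  strategy <- match.arg(strategy)
  if (strategy == "random_fraction" &&
      (fraction <= 0 || fraction >= 1)) stop("fraction must be in (0, 1)")
  structure(list(strategy = strategy, fraction = fraction,
                 repeats = as.integer(repeats), seed = as.integer(seed),
                 test_days = test_days),
            class = "split_plan")
}

#' @rdname split_plan
#' @param dataset a [gesture_dataset()].
#' @param plan a `split_plan`.
#' @return `make_splits()` returns a list of splits, each a list with
#'   `reference` and `test` gesture datasets (always disjoint).
#' @export
make_splits <- function(dataset, plan) {
  stopifnot(inherits(plan, "split_plan"))
  info <- dataset$info
  if (plan$strategy == "leave_days_out") {
    days <- sort(unique(info$seating))
    held <- if (is.null(plan$test_days)) as.list(days) else plan$test_days
    return(lapply(held, function(d) {
      unknown <- setdiff(d, days)
      if (length(unknown))
        stop("unknown seating id(s): ", paste(unknown, collapse = ", "))
      test_idx <- info$seating %in% d
      list(reference = subset_dataset(dataset, !test_idx),
           test = subset_dataset(dataset, test_idx))
    }))
  }
  set.seed(plan$seed)
  lapply(seq_len(plan$repeats), function(r) {
    ref_idx <- logical(nrow(info))
    for (l in unique(info$label)) {
      idx <- which(info$label == l)
      n_ref <- round(plan$fraction * length(idx))
      ref_idx[sample(idx, n_ref)] <- TRUE
    }
    list(reference = subset_dataset(dataset, ref_idx),
         test = subset_dataset(dataset, !ref_idx))
  })
}

#' Subsample the reference set per day
#'
#' Uniformly draws the same number of samples per gesture and per seating
#' from a reference dataset — used to ask how few reference recordings
#' still sustain accuracy (e.g. 3 samples per day over 4 days = 12 per
#' gesture).
#'
#' @param dataset a reference [gesture_dataset()].
#' @param s samples to keep per (gesture, seating) cell.
#' @param seed RNG seed.
#' @return a smaller [gesture_dataset()].
#' @export
subsample_reference_per_day <- function(dataset, s, seed = 1L) {
  if (s < 1L) stop("s must be >= 1")
  set.seed(seed)
  info <- dataset$info
  keep <- integer(0)
  for (l in unique(info$label)) for (d in sort(unique(info$seating))) {
    idx <- which(info$label == l & info$seating == d)
    if (length(idx) < s)
      stop("only ", length(idx), " samples for gesture ", l, " on seating ",
           d, "; cannot keep ", s)
    keep <- c(keep, if (length(idx) == 1L) idx else sample(idx, s))
  }
  subset_dataset(dataset, sort(keep))
}

#' Sweep acceptance cutoffs over intracluster percentiles
#'
#' For each split of the data and each reference mode, builds the reference
#' set, derives per-gesture cutoffs at each percentile of the reference
#' intracluster distributions, classifies the test set once (distances are
#' reused across percentiles) and aggregates the acceptance metrics across
#' splits.
#'
#' @param dataset a [gesture_dataset()].
#' @param plan a [split_plan()].
#' @param modes subset of `c("uncondensed", "rep", "dba")`.
#' @param percentiles cutoff grid in \[0, 100\] (default 5, 10, ..., 100).
#' @inheritParams build_reference_set
#' @return data frame with one row per (mode, percentile): mean and
#'   standard error (sd / sqrt(splits)) of alpha, beta and gamma across
#'   splits.
#' @export
sweep_cutoffs <- function(dataset, plan,
                          modes = c("uncondensed", "rep", "dba"),
                          percentiles = seq(5, 100, by = 5),
                          cost = "euclidean", normalize = TRUE,
                          max_iter = 30L, tol = 1e-6,
                          cutoff_source = c("pairwise", "to_reference")) {
  if (any(percentiles < 0 | percentiles > 100))
    stop("percentiles must lie in [0, 100]")
  cutoff_source <- match.arg(cutoff_source)
  modes <- match.arg(modes, c("uncondensed", "rep", "dba"),
                     several.ok = TRUE)
  splits <- make_splits(dataset, plan)
  acc <- list()
  for (si in seq_along(splits)) {
    sp <- splits[[si]]
    dm <- lapply(clusters(sp$reference), function(cl)
      if (length(cl) >= 2L)
        dtw_distance_matrix(cl, cost = cost, normalize = normalize)
      else matrix(0, 1, 1))
    for (mode in modes) {
      refs <- build_reference_set(sp$reference, mode, cost = cost,
                                  normalize = normalize, max_iter = max_iter,
                                  tol = tol, cutoff_source = cutoff_source,
                                  cluster_distmats = dm)
      res <- classify_dataset(sp$test, refs)
      for (p in percentiles) {
        cut <- cutoffs_from_percentile(refs, p)
        accepted <- res$nearest_distance <= cut[res$nearest_label]
        correct <- accepted & res$predicted == res$truth
        m <- acceptance_metrics(sum(correct), sum(accepted), nrow(res))
        acc[[length(acc) + 1L]] <- data.frame(
          split = si, mode = mode, percentile = p,
          alpha = m$alpha, beta = m$beta, gamma = m$gamma,
          stringsAsFactors = FALSE)
      }
    }
  }
  acc <- do.call(rbind, acc)
  agg <- function(v) c(mean = mean(v, na.rm = TRUE),
                       se = stats::sd(v, na.rm = TRUE) /
                         sqrt(sum(!is.na(v))))
  out <- list()
  for (mode in unique(acc$mode)) for (p in percentiles) {
    sub <- acc[acc$mode == mode & acc$percentile == p, ]
    a <- agg(sub$alpha); b <- agg(sub$beta); g <- agg(sub$gamma)
    out[[length(out) + 1L]] <- data.frame(
      mode = mode, percentile = p,
      alpha_mean = a[["mean"]], alpha_se = a[["se"]],
      beta_mean = b[["mean"]], beta_se = b[["se"]],
      gamma_mean = g[["mean"]], gamma_se = g[["se"]],
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
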