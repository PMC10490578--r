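#' Intra- and intercluster distance distributions
#'
#' The intracluster distribution delta_k collects the DTW distance of every
#' unordered pair of samples within one gesture cluster (n(n-1)/2 values);
#' its upper percentiles proxy the cluster's diameter. The intercluster
#' distribution Delta_kl collects the distance of every sample of cluster k
#' to every sample of cluster l (n*m values); its lower percentiles proxy
#' the border-to-border distance of the two clusters. The space is
#' non-metric, but these distributions still support a geometric reading of
#' why nearest-neighbor classification works.
#'
#' @param samples,samplesK,samplesL lists of series matrices (clusters).
#' @inheritParams dtw_align
#' @param normalize use length-normalized DTW (default)?
#' @return numeric vector of distances.
#' @examples
#' cl <- list(matrix(0, 1, 1), matrix(1, 1, 1), matrix(3, 1, 1))
#' sort(intracluster_distances(cl)) # c(1, 2, 3) / sqrt(2)
#' @export
intracluster_distances <- function(samples, cost = "euclidean",
                                   normalize = TRUE) {
  if (length(samples) < 2L)
    stop("intracluster distances need a cluster of at least 2 samples")
  D <- dtw_distance_matrix(samples, cost = cost, normalize = normalize)
  D[upper.tri(D)]
}

#' @rdname intracluster_distances
#' @export
intercluster_distances <- function(samplesK, samplesL, cost = "euclidean",
                                   normalize = TRUE) {
  if (length(samplesK) == 0L || length(samplesL) == 0L)
    stop("intercluster distances need two non-empty clusters")
  D <- dtw_distance_matrix(samplesK, samplesL, cost = cost,
                           normalize = normalize)
  as.vector(D)
}

#' Percentile of a distance distribution
#'
#' Linear-interpolation percentile (the convention of [stats::quantile()]
#' type 7): p = 0 gives the minimum, p = 100 the maximum, and the value is
#' interpolated between order statistics in between. Fixed package-wide so
#' percentile-cutoff sweeps are reproducible.
#'
#' @param values non-empty numeric vector.
#' @param p percent in \[0, 100\].
#' @return a single number.
#' @examples
#' dist_percentile(c(0, 10), 50) # 5
#' @export
dist_percentile <- function(values, p) {
  if (length(values) == 0L) stop("empty distribution has no percentiles")
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 100)
    stop("p must be a single percent in [0, 100]")
  unname(stats::quantile(values, probs = p / 100, type = 7, names = FALSE))
}

#' Pairwise separability report
#'
#' For every ordered pair of gesture clusters (k, l) the margin
#' `m_kl = p10(Delta_kl) - p90(delta_k)` compares the 10th percentile of
#' the intercluster distances with the 90th percentile of cluster k's
#' intracluster distances. A positive margin means the outer layer of
#' cluster k ends before the nearest samples of cluster l begin — the
#' separation mechanism behind high 1-NN accuracy. Pairs with margin <= 0
#' are flagged as weakly separated. Both directions are reported because
#' delta_k and delta_l differ.
#'
#' @param dataset a [gesture_dataset()] with every cluster of size >= 2,
#'   or a named list of clusters (lists of series).
#' @inheritParams intracluster_distances
#' @param percentiles length-2 vector: the intercluster (lower) and
#'   intracluster (upper) percentiles used for the margin, default c(10, 90).
#' @return data frame with one row per ordered pair: `k`, `l`, percentile
#'   summaries of delta_k and Delta_kl, `margin`, and `weak` flag.
#' @export
separability_report <- function(dataset, cost = "euclidean",
                                normalize = TRUE, percentiles = c(10, 90)) {
  cls <- if (inherits(dataset, "gesture_dataset")) clusters(dataset)
         else dataset
  if (length(cls) < 2L) stop("separability needs at least two clusters")
  if (is.null(names(cls))) names(cls) <- paste0("cluster", seq_along(cls))
  sizes <- vapply(cls, length, integer(1))
  if (any(sizes < 2L)) stop("every cluster must have at least 2 samples")
  labs <- names(cls)
  delta <- lapply(cls, intracluster_distances, cost = cost,
                  normalize = normalize)
  rows <- list()
  for (k in labs) for (l in labs) {
    if (k == l) next
    Delta <- intercluster_distances(cls[[k]], cls[[l]], cost = cost,
                                    normalize = normalize)
    m <- dist_percentile(Delta, percentiles[1]) -
      dist_percentile(delta[[k]], percentiles[2])
    rows[[length(rows) + 1L]] <- data.frame(
      k = k, l = l,
      delta_p10 = dist_percentile(delta[[k]], 10),
      delta_p50 = dist_percentile(delta[[k]], 50),
      delta_p90 = dist_percentile(delta[[k]], 90),
      Delta_p10 = dist_percentile(Delta, 10),
      Delta_p50 = dist_percentile(Delta, 50),
      Delta_p90 = dist_percentile(Delta, 90),
      margin = m,
      weak = m <= 0,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Select a well-separated gesture subset
#'
#' From a pool of gesture clusters, picks the `n` labels whose induced set
#' of ordered-pair margins `p10(Delta_kl) - p90(delta_k)` has the largest
#' minimum — the maximin-margin subset, found by exhaustive search over all
#' subsets (pools here are small). Users recording more gestures than they
#' need can use this to keep the most mutually distinguishable ones.
#'
#' @inheritParams separability_report
#' @param n subset size, between 1 and the number of clusters.
#' @param report optional precomputed [separability_report()] (saves the
#'   distance computations).
#' @return character vector of `n` labels, sorted; attribute
#'   `"min_margin"` carries the achieved maximin value (`Inf` for n = 1).
#'   Ties are broken toward the lexicographically first subset.
#' @export
select_gesture_subset <- function(dataset, n, cost = "euclidean",
                                  normalize = TRUE, report = NULL) {
  if (is.null(report))
    report <- separability_report(dataset, cost = cost, normalize = normalize)
  labs <- sort(unique(report$k))
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n > length(labs))
    stop("n must be between 1 and the number of clusters (", length(labs), ")")
  n <- as.integer(n)
  if (n == 1L) {
    out <- labs[1L]
    attr(out, "min_margin") <- Inf
    return(out)
  }
  key <- paste(report$k, report$l, sep = "\r")
  margin_of <- stats::setNames(report$margin, key)
  combos <- utils::combn(labs, n, simplify = FALSE)
  best <- NULL; best_val <- -Inf
  for (s in combos) {
    pairs <- expand.grid(k = s, l = s, stringsAsFactors = FALSE)
    pairs <- pairs[pairs$k != pairs$l, ]
    val <- min(margin_of[paste(pairs$k, pairs$l, sep = "\r")])
    if (val > best_val) { best_val <- val; best <- s }
  }
  out <- sort(best)
  attr(out, "min_margin") <- best_val
  out
}
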