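#' Cluster condensing: representative selection and barycenter averaging
#'
#' Both condensing methods reduce a gesture cluster to a single reference
#' series, cutting the per-query cost of nearest-neighbor classification
#' from one DTW per stored sample to one per gesture.
#'
#' The one-step method ("rep") selects the cluster member whose median
#' distance to all other members is smallest. The two-step method ("dba")
#' uses that representative as the initial guess for DTW barycenter
#' averaging, which iteratively builds an artificial series minimizing the
#' summed squared DTW distance to the cluster — it need not equal any
#' member.
#'
#' @param samples list of series matrices forming one cluster.
#' @param distmat optional precomputed symmetric distance matrix over
#'   `samples` (saves recomputation when the caller already has it).
#' @inheritParams dtw_align
#' @param normalize use length-normalized DTW distances (default)?
#' @return `select_representative()` returns a list with `index` (position
#'   of the chosen member), `series`, and `median_distance`.
#' @details Ties on the median are broken by input order (earliest sample
#'   wins); the median of an even count is the mean of the two central
#'   values. A singleton cluster is its own representative.
#' @examples
#' cl <- list(matrix(0, 1, 3), matrix(c(0, 0, 1), 1), matrix(2, 1, 3))
#' select_representative(cl)$index
#' @export
select_representative <- function(samples, distmat = NULL,
                                  cost = "euclidean", normalize = TRUE) {
  if (!is.list(samples) || length(samples) == 0L)
    stop("cluster must be a non-empty list of series")
  n <- length(samples)
  if (n == 1L)
    return(list(index = 1L, series = mc_series(samples[[1]]),
                median_distance = 0))
  if (is.null(distmat))
    distmat <- dtw_distance_matrix(samples, cost = cost, normalize = normalize)
  med <- vapply(seq_len(n),
                function(i) stats::median(distmat[i, -i]), numeric(1))
  idx <- which.min(med) # which.min returns the earliest minimum
  list(index = idx, series = mc_series(samples[[idx]]),
       median_distance = med[idx])
}

#' @rdname select_representative
#' @param init initial barycenter series (typically the representative);
#'   the barycenter keeps this length throughout.
#' @param max_iter iteration cap.
#' @param tol stop when the maximum absolute frame change falls below this.
#' @return `dba_barycenter()` returns the barycenter series with attribute
#'   `"objective_trace"`: the within-cluster sum of squares — each member's
#'   DTW alignment cost to the barycenter under the squared-Euclidean frame
#'   cost — after each alignment. Re-aligning can only lower each member's
#'   cost and the frame-mean update minimizes the squared deviations along
#'   the fixed alignments, so the trace is non-increasing.
#' @details Barycenter averaging aligns every member to the current
#'   barycenter (squared-Euclidean frame cost, the metric whose
#'   frame-association average is exactly the minimizer), then replaces
#'   each barycenter frame by the mean of all member frames associated with
#'   it, and repeats until the barycenter stops moving.
#' @export
dba_barycenter <- function(samples, init, max_iter = 30L, tol = 1e-6) {
  if (!is.list(samples) || length(samples) == 0L)
    stop("cluster must be a non-empty list of series")
  samples <- lapply(samples, mc_series)
  bary <- mc_series(init)
  check_same_channels(bary, samples[[1]])
  C <- nrow(bary); Lb <- ncol(bary)
  trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    sums <- matrix(0, C, Lb)
    counts <- numeric(Lb)
    obj <- 0
    for (g in samples) {
      al <- cpp_dtw_path(bary, g, 2L) # squared-euclidean frame cost
      obj <- obj + al$raw_cost
      p <- al$path
      for (k in seq_len(nrow(p))) {
        i <- p[k, 1]
        sums[, i] <- sums[, i] + g[, p[k, 2]]
        counts[i] <- counts[i] + 1
      }
    }
    trace <- c(trace, obj)
    new_bary <- sweep(sums, 2, counts, "/") # every position is on some path
    delta <- max(abs(new_bary - bary))
    bary <- new_bary
    if (delta < tol) break
  }
  attr(bary, "objective_trace") <- trace
  bary
}

#' Condense every cluster of a dataset
#'
#' Applies one of the condensing methods to each gesture cluster and
#' returns one reference series per label. For `method = "dba"` the
#' representative is selected first and used as the barycenter's initial
#' guess (the two-step procedure).
#'
#' @param dataset a [gesture_dataset()].
#' @param method `"rep"` or `"dba"`.
#' @inheritParams select_representative
#' @inheritParams dba_barycenter
#' @return named list (by label) of reference series; attribute `"method"`
#'   records how they were built.
#' @export
condense_dataset <- function(dataset, method = c("rep", "dba"),
                             cost = "euclidean", normalize = TRUE,
                             max_iter = 30L, tol = 1e-6) {
  method <- match.arg(method)
  cls <- clusters(dataset)
  out <- lapply(cls, function(cl) {
    rep <- select_representative(cl, cost = cost, normalize = normalize)
    if (method == "rep") return(rep$series)
    dba_barycenter(cl, rep$series, max_iter = max_iter, tol = tol)
  })
  attr(out, "method") <- method
  out
}
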