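#' Dynamic time warping with a restricted step set
#'
#' Aligns two multichannel series by the dynamic program over warping paths
#' whose consecutive steps are restricted to \{(1,0), (0,1), (1,1)\}, with
#' both endpoints fixed: the first path pair aligns the first frames and the
#' last pair the last frames, and both index components are non-decreasing,
#' so series are never warped backwards. The raw DTW distance is the minimal
#' accumulated frame cost over all admissible paths.
#'
#' The length-normalized distance divides the raw cost by
#' `sqrt(N^2 + M^2)` — the diagonal of the N x M cost matrix — removing the
#' bias that makes plain accumulated cost prefer shorter sequences.
#'
#' When two or more predecessors of a cell tie, the returned path prefers
#' the diagonal step, then the step advancing in `X`, then the step
#' advancing in `Y`; the path is therefore deterministic (the barycenter
#' averaging in [dba_barycenter()] relies on this).
#'
#' @param X,Y series matrices (channels x frames) with equal channel count.
#' @param cost `"euclidean"` (default), `"manhattan"`, or a function taking
#'   two channel vectors and returning a non-negative scalar. Named costs
#'   run in compiled code; a function cost falls back to an R-level dynamic
#'   program.
#' @return `dtw_align()` returns a list of class `"dtw_alignment"` with
#'   elements `raw_cost`, `normalized_distance` and `path` (an L x 2 matrix
#'   of 1-based index pairs into `X` and `Y`).
#' @examples
#' X <- matrix(c(0, 0), 1)
#' Y <- matrix(c(0, 1), 1)
#' dtw_align(X, Y)$raw_cost            # 1
#' normalized_dtw(X, Y)                # 1 / sqrt(8)
#' @seealso [brute_force_dtw()] for the exhaustive-enumeration oracle.
#' @export
dtw_align <- function(X, Y, cost = "euclidean") {
  X <- mc_series(X); Y <- mc_series(Y)
  check_same_channels(X, Y)
  code <- cost_code(cost)
  if (is.null(code)) {
    res <- r_dtw_path(X, Y, cost_fun(cost))
  } else {
    res <- cpp_dtw_path(X, Y, code)
  }
  structure(
    list(raw_cost = res$raw_cost,
         normalized_distance = res$raw_cost / diag_norm(ncol(X), ncol(Y)),
         path = res$path),
    class = "dtw_alignment")
}

#' @export
print.dtw_alignment <- function(x, ...) {
  cat("DTW alignment: raw cost", format(x$raw_cost),
      "| normalized", format(x$normalized_distance),
      "| path length", nrow(x$path), "\n")
  invisible(x)
}

diag_norm <- function(N, M) sqrt(N^2 + M^2)

#' @rdname dtw_align
#' @param normalize divide the raw cost by the cost-matrix diagonal?
#' @return `dtw_distance()` and `normalized_dtw()` return a single
#'   non-negative number.
#' @export
dtw_distance <- function(X, Y, cost = "euclidean", normalize = TRUE) {
  X <- mc_series(X); Y <- mc_series(Y)
  check_same_channels(X, Y)
  code <- cost_code(cost)
  raw <- if (is.null(code)) r_dtw_path(X, Y, cost_fun(cost))$raw_cost
         else cpp_dtw_cost(X, Y, code)
  if (normalize) raw / diag_norm(ncol(X), ncol(Y)) else raw
}

#' @rdname dtw_align
#' @export
normalized_dtw <- function(X, Y, cost = "euclidean") {
  dtw_distance(X, Y, cost = cost, normalize = TRUE)
}

# R-level DP, used only for closure costs (and as a slow reference).
r_dtw_path <- function(X, Y, fc) {
  N <- ncol(X); M <- ncol(Y)
  local_cost <- matrix(0, N, M)
  for (i in seq_len(N)) for (j in seq_len(M))
    local_cost[i, j] <- fc(X[, i], Y[, j])
  D <- matrix(Inf, N, M)
  D[1, 1] <- local_cost[1, 1]
  for (i in seq_len(N)) for (j in seq_len(M)) {
    if (i == 1 && j == 1) next
    prev <- Inf
    if (i > 1 && j > 1) prev <- min(prev, D[i - 1, j - 1])
    if (i > 1) prev <- min(prev, D[i - 1, j])
    if (j > 1) prev <- min(prev, D[i, j - 1])
    D[i, j] <- prev + local_cost[i, j]
  }
  i <- N; j <- M
  rev_path <- list(c(i, j))
  while (i > 1 || j > 1) {
    if (i == 1) { j <- j - 1 }
    else if (j == 1) { i <- i - 1 }
    else {
      diag <- D[i - 1, j - 1]; up <- D[i - 1, j]; left <- D[i, j - 1]
      if (diag <= up && diag <= left) { i <- i - 1; j <- j - 1 }
      else if (up <= left) i <- i - 1
      else j <- j - 1
    }
    rev_path[[length(rev_path) + 1L]] <- c(i, j)
  }
  path <- do.call(rbind, rev(rev_path))
  list(raw_cost = D[N, M], path = path)
}

#' Exhaustive-path DTW oracle
#'
#' Enumerates every admissible warping path between two short series and
#' returns the minimal summed frame cost. Completely independent of the
#' dynamic program in [dtw_align()], so it serves as its test oracle. The
#' number of admissible paths grows like the Delannoy numbers, so lengths
#' are capped.
#'
#' @inheritParams dtw_align
#' @param max_len refuse series longer than this (default 8).
#' @return minimal raw cost over all enumerated paths.
#' @export
brute_force_dtw <- function(X, Y, cost = "euclidean", max_len = 8L) {
  X <- mc_series(X); Y <- mc_series(Y)
  check_same_channels(X, Y)
  N <- ncol(X); M <- ncol(Y)
  if (N > max_len || M > max_len)
    stop("brute-force oracle refuses series longer than ", max_len, " frames")
  fc <- cost_fun(cost)
  paths <- enumerate_paths(N, M)
  best <- Inf
  for (p in paths) {
    tot <- 0
    for (k in seq_len(nrow(p))) tot <- tot + fc(X[, p[k, 1]], Y[, p[k, 2]])
    if (tot < best) best <- tot
  }
  best
}

# All monotone step-restricted paths from (1,1) to (N,M).
enumerate_paths <- function(N, M) {
  out <- list()
  grow <- function(path, i, j) {
    if (i == N && j == M) {
      out[[length(out) + 1L]] <<- do.call(rbind, path)
      return(invisible())
    }
    if (i < N && j < M) grow(c(path, list(c(i + 1, j + 1))), i + 1, j + 1)
    if (i < N) grow(c(path, list(c(i + 1, j))), i + 1, j)
    if (j < M) grow(c(path, list(c(i, j + 1))), i, j + 1)
  }
  grow(list(c(1L, 1L)), 1L, 1L)
  out
}

#' Validate a warping path
#'
#' Checks endpoint matching, monotonicity and the restricted step set for a
#' path aligning series of lengths `N` and `M`.
#'
#' @param path L x 2 integer matrix of 1-based index pairs.
#' @param N,M lengths of the two aligned series.
#' @return `TRUE` invisibly; stops with a message otherwise.
#' @export
validate_warping_path <- function(path, N, M) {
  if (!is.matrix(path) || ncol(path) != 2L) stop("path must be an L x 2 matrix")
  if (!all(path[1, ] == c(1L, 1L))) stop("path must start at (1, 1)")
  if (!all(path[nrow(path), ] == c(N, M))) stop("path must end at (N, M)")
  if (nrow(path) > 1L) {
    steps <- diff(path)
    ok <- (steps[, 1] %in% 0:1) & (steps[, 2] %in% 0:1) & rowSums(steps) >= 1
    if (!all(ok)) stop("path steps must be one of (1,0), (0,1), (1,1)")
  }
  invisible(TRUE)
}

#' DTW distance matrices
#'
#' Computes all normalized (or raw) DTW distances between two collections of
#' series, or all pairwise distances within one collection, in compiled code.
#'
#' @param A,B lists of series matrices; with `B = NULL` the symmetric
#'   pairwise matrix within `A` is returned (zero diagonal).
#' @inheritParams dtw_align
#' @param normalize divide each raw cost by its cost-matrix diagonal?
#' @return numeric matrix, `length(A)` x `length(B)` (or square).
#' @export
dtw_distance_matrix <- function(A, B = NULL, cost = "euclidean",
                                normalize = TRUE) {
  A <- lapply(A, mc_series)
  code <- cost_code(cost)
  if (is.null(code))
    stop("distance matrices support only the named compiled costs")
  if (is.null(B)) return(cpp_dtw_pairwise(A, code, normalize))
  B <- lapply(B, mc_series)
  cpp_dtw_cross(A, B, code, normalize)
}
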