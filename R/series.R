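#' Multichannel series constructor
#'
#' A gesture recording is a numeric matrix with one row per sensor channel
#' and one column per time frame (intensity units as emitted by the sensor).
#' `mc_series()` validates a matrix and returns it unchanged, so downstream
#' code can rely on finiteness and non-degenerate shape.
#'
#' @param values numeric matrix, channels x frames.
#' @return the validated matrix.
#' @examples
#' x <- mc_series(matrix(rnorm(16), nrow = 8))
#' n_channels(x)
#' @export
mc_series <- function(values) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("a series must be a numeric matrix (channels x frames)")
  if (nrow(values) < 1L || ncol(values) < 1L)
    stop("a series needs at least one channel and one frame")
  if (!all(is.finite(values)))
    stop("series values must all be finite")
  storage.mode(values) <- "double"
  values
}

#' @rdname mc_series
#' @param x a series matrix.
#' @export
n_channels <- function(x) nrow(x)

#' @rdname mc_series
#' @export
n_frames <- function(x) ncol(x)

check_same_channels <- function(X, Y) {
  if (nrow(X) != nrow(Y))
    stop("series have different channel counts (", nrow(X), " vs ", nrow(Y), ")")
  invisible(TRUE)
}

#' Frame-level costs
#'
#' Cost between two single frames (C-dimensional sensor snapshots). The
#' Euclidean norm across channels is the default cost underlying all DTW
#' distances in this package; the per-channel absolute-difference sum
#' ("manhattan") is available as an alternative.
#'
#' @param x,y numeric vectors of equal length (one value per channel).
#' @return a non-negative scalar, zero iff the frames are equal.
#' @examples
#' frame_cost_euclidean(c(3, 4), c(0, 0)) # 5
#' @export
frame_cost_euclidean <- function(x, y) {
  if (length(x) != length(y)) stop("frames have different channel counts")
  sqrt(sum((x - y)^2))
}

#' @rdname frame_cost_euclidean
#' @export
frame_cost_manhattan <- function(x, y) {
  if (length(x) != length(y)) stop("frames have different channel counts")
  sum(abs(x - y))
}

# Map a cost spec (name or function) to the C++ dispatch code, or NULL for
# an R-level closure.
cost_code <- function(cost) {
  if (is.function(cost)) return(NULL)
  cost <- match.arg(cost, c("euclidean", "manhattan"))
  if (cost == "euclidean") 0L else 1L
}

cost_fun <- function(cost) {
  if (is.function(cost)) return(cost)
  cost <- match.arg(cost, c("euclidean", "manhattan"))
  if (cost == "euclidean") frame_cost_euclidean else frame_cost_manhattan
}
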