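#' Maximum-voluntary-contraction ("powergrip") normalization factors
#'
#' Estimates a participant's maximum signal strength per sensor from
#' powergrip recordings: gripping as hard as possible for as long as the
#' contraction can be held. Each recording is cut into three equal thirds
#' and only the center third is kept — the first third excludes the ramp-up
#' to full contraction, the last third excludes the tiring-out phase. The
#' kept frames are averaged over time and over recordings per channel,
#' giving the per-sensor factors; their mean is the batch factor.
#'
#' For a recording of length L the center third consists of the frames with
#' 0-based indices in `[floor(L/3), floor(2L/3))` (half-open).
#'
#' @param recordings list of series matrices (each at least 3 frames).
#' @return object of class `"normalization_factors"`: list with
#'   `per_sensor` (length-C vector) and `batch` (scalar mean). All factors
#'   must come out positive; degenerate recordings are an error.
#' @export
powergrip_factors <- function(recordings) {
  if (!is.list(recordings) || length(recordings) == 0L)
    stop("need at least one powergrip recording")
  recordings <- lapply(recordings, mc_series)
  per_rec <- lapply(recordings, function(r) {
    L <- ncol(r)
    if (L < 3L) stop("powergrip recordings must have at least 3 frames")
    idx <- (floor(L / 3) + 1L):floor(2 * L / 3)
    rowMeans(r[, idx, drop = FALSE])
  })
  per_sensor <- Reduce(`+`, per_rec) / length(per_rec)
  if (any(per_sensor <= 0))
    stop("non-positive normalization factor; powergrip recordings degenerate")
  structure(list(per_sensor = per_sensor, batch = mean(per_sensor)),
            class = "normalization_factors")
}

#' @export
print.normalization_factors <- function(x, ...) {
  cat("Powergrip factors: batch", format(x$batch), "| per sensor:",
      paste(format(x$per_sensor, digits = 4), collapse = " "), "\n")
  invisible(x)
}

#' Inter-participant amplitude normalization
#'
#' Two schemes correct for the different overall muscle-signal amplitudes
#' of different participants. Batch normalization divides every value by
#' the average maximum signal strength (one scalar), damping the effect of
#' pronounced overall physique; sensor normalization divides each channel
#' by that sensor's own maximum, additionally correcting inhomogeneous
#' muscle structure. The two coincide when all per-sensor factors are
#' equal. Both are positive scalings, so shapes are preserved and (for the
#' Euclidean frame cost) batch normalization scales all DTW distances by
#' exactly 1 / batch factor.
#'
#' @param sample a series matrix.
#' @param factors a [powergrip_factors()] object.
#' @return the rescaled series.
#' @export
batch_normalize <- function(sample, factors) {
  stopifnot(inherits(factors, "normalization_factors"))
  if (factors$batch <= 0) stop("batch factor must be positive")
  mc_series(sample) / factors$batch
}

#' @rdname batch_normalize
#' @export
sensor_normalize <- function(sample, factors) {
  stopifnot(inherits(factors, "normalization_factors"))
  sample <- mc_series(sample)
  if (length(factors$per_sensor) != nrow(sample))
    stop("factor count does not match channel count")
  if (any(factors$per_sensor <= 0)) stop("all per-sensor factors must be positive")
  sample / factors$per_sensor
}

#' @rdname batch_normalize
#' @param dataset a [gesture_dataset()].
#' @param scheme `"batch"`, `"sensor"` or `"none"`.
#' @export
normalize_dataset <- function(dataset, factors,
                              scheme = c("batch", "sensor", "none")) {
  scheme <- match.arg(scheme)
  if (scheme == "none") return(dataset)
  f <- switch(scheme, batch = batch_normalize, sensor = sensor_normalize)
  dataset$samples <- lapply(dataset$samples, f, factors = factors)
  dataset
}

#' Within- vs between-subject distance distributions
#'
#' For each gesture present in both datasets: the within-subject
#' intracluster distances delta for each subject and the cross-subject
#' distribution Delta of all pairs of that gesture across the two subjects,
#' after applying the chosen normalization with each subject's own
#' factors. If the same gesture of two subjects is about as far apart as
#' different gestures of one subject, direct transfer of reference data
#' between subjects fails; successful normalization would pull Delta down
#' into the range of the deltas.
#'
#' @param datasetA,datasetB one [gesture_dataset()] per subject.
#' @param normalization `"none"`, `"batch"` or `"sensor"`.
#' @param factorsA,factorsB each subject's own [powergrip_factors()]
#'   (required unless `normalization = "none"`).
#' @inheritParams dtw_align
#' @param normalize use length-normalized DTW (default)?
#' @return named list per gesture, each with numeric vectors `delta_A`,
#'   `delta_B`, `Delta_AB`. Gestures present in only one dataset are
#'   skipped with a warning.
#' @export
interparticipant_distributions <- function(datasetA, datasetB,
                                           normalization = c("none", "batch",
                                                             "sensor"),
                                           factorsA = NULL, factorsB = NULL,
                                           cost = "euclidean",
                                           normalize = TRUE) {
  normalization <- match.arg(normalization)
  if (normalization != "none" && (is.null(factorsA) || is.null(factorsB)))
    stop("normalization needs each subject's own powergrip factors")
  if (normalization != "none") {
    datasetA <- normalize_dataset(datasetA, factorsA, normalization)
    datasetB <- normalize_dataset(datasetB, factorsB, normalization)
  }
  clsA <- clusters(datasetA); clsB <- clusters(datasetB)
  common <- intersect(names(clsA), names(clsB))
  only <- setdiff(union(names(clsA), names(clsB)), common)
  if (length(only))
    warning("gesture(s) present in only one dataset, skipped: ",
            paste(only, collapse = ", "))
  out <- lapply(common, function(g) {
    list(delta_A = intracluster_distances(clsA[[g]], cost = cost,
                                          normalize = normalize),
         delta_B = intracluster_distances(clsB[[g]], cost = cost,
                                          normalize = normalize),
         Delta_AB = intercluster_distances(clsA[[g]], clsB[[g]], cost = cost,
                                           normalize = normalize))
  })
  names(out) <- common
  out
}
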