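#' Labeled gesture datasets
#'
#' A gesture dataset couples a list of recordings (channels x frames
#' matrices, lengths may differ) with per-sample metadata: the gesture
#' label, a subject id and a seating id (one physical placement of the
#' sensor armband; re-seating perturbs sensor positions, so seatings play
#' the role of recording days).
#'
#' @param samples list of series matrices, all with the same channel count.
#' @param label character vector of gesture labels, one per sample.
#' @param subject,seating per-sample metadata (recycled if scalar).
#' @param sampling_rate acquisition rate in Hz, carried as metadata only —
#'   all distances are sample-index based.
#' @return an object of class `"gesture_dataset"`.
#' @export
gesture_dataset <- function(samples, label, subject = "s1", seating = 1L,
                            sampling_rate = 200) {
  if (!is.list(samples) || length(samples) == 0L)
    stop("samples must be a non-empty list of series matrices")
  samples <- lapply(samples, mc_series)
  n <- length(samples)
  ch <- vapply(samples, nrow, integer(1))
  if (length(unique(ch)) != 1L)
    stop("all samples must share the channel count")
  info <- data.frame(
    label = rep_len(as.character(label), n),
    subject = rep_len(as.character(subject), n),
    seating = rep_len(as.integer(seating), n),
    stringsAsFactors = FALSE)
  structure(list(samples = samples, info = info,
                 sampling_rate = sampling_rate),
            class = "gesture_dataset")
}

#' @export
print.gesture_dataset <- function(x, ...) {
  cat("Gesture dataset:", length(x$samples), "samples,",
      length(unique(x$info$label)), "gestures,",
      length(unique(x$info$seating)), "seating(s),",
      nrow(x$samples[[1]]), "channels @", x$sampling_rate, "Hz\n")
  print(table(label = x$info$label, seating = x$info$seating))
  invisible(x)
}

#' @rdname gesture_dataset
#' @param x a gesture dataset.
#' @export
n_samples <- function(x) length(x$samples)

#' @rdname gesture_dataset
#' @export
dataset_labels <- function(x) sort(unique(x$info$label))

#' @rdname gesture_dataset
#' @param i integer or logical index over samples.
#' @export
subset_dataset <- function(x, i) {
  if (is.logical(i)) i <- which(i)
  if (length(i) == 0L) stop("subset would produce an empty dataset")
  gesture_dataset(x$samples[i], x$info$label[i], x$info$subject[i],
                  x$info$seating[i], x$sampling_rate)
}

#' @rdname gesture_dataset
#' @return `clusters()` returns a named list (one element per gesture label,
#'   in sorted label order) of lists of series — the gesture clusters G_k.
#' @export
clusters <- function(x) {
  labs <- dataset_labels(x)
  out <- lapply(labs, function(l) x$samples[x$info$label == l])
  names(out) <- labs
  out
}
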