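#' Read and write gesture recordings
#'
#' Recordings are stored as delimited text: a header row naming the
#' channels (`ch1`, `ch2`, ...), then one row per time frame with one
#' numeric column per channel, comma separated, full float precision.
#' `write_recording()` followed by `read_recording()` round-trips values
#' bit-identically.
#'
#' @param path file path.
#' @return `read_recording()` returns a series matrix (channels x frames).
#' @export
read_recording <- function(path) {
  if (!file.exists(path)) stop("no such recording file: ", path)
  lines <- readLines(path)
  if (length(lines) < 2L) stop("recording file has no data rows: ", path)
  header <- strsplit(lines[1L], ",", fixed = TRUE)[[1L]]
  C <- length(header)
  rows <- lapply(seq_along(lines)[-1L], function(i) {
    fields <- strsplit(lines[i], ",", fixed = TRUE)[[1L]]
    if (length(fields) != C)
      stop("line ", i, " of ", path, ": expected ", C, " columns, found ",
           length(fields))
    vals <- suppressWarnings(as.numeric(fields))
    if (anyNA(vals))
      stop("line ", i, " of ", path, ": non-numeric cell '",
           fields[which(is.na(vals))[1L]], "'")
    vals
  })
  mc_series(t(do.call(rbind, rows)))
}

#' @rdname read_recording
#' @param series a series matrix.
#' @export
write_recording <- function(series, path) {
  series <- mc_series(series)
  C <- nrow(series)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(paste0("ch", seq_len(C)), collapse = ","), con)
  frames <- apply(series, 2, function(fr)
    paste(format(fr, digits = 17, trim = TRUE, scientific = FALSE),
          collapse = ","))
  writeLines(frames, con)
  invisible(path)
}

#' Dataset directories with a manifest
#'
#' A dataset directory holds one recording file per sample plus a
#' `manifest.csv` listing, per sample: relative file path, gesture label,
#' subject, seating id, length and channel count. Dataset-level metadata
#' (sampling rate) is stored in `meta.json`. `load_dataset()` validates
#' every sample against the manifest and reports all offenders at once.
#'
#' @param dataset a [gesture_dataset()].
#' @param dir directory to create/read.
#' @return `write_dataset()` returns `dir` invisibly; `load_dataset()`
#'   returns a [gesture_dataset()].
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "gesture_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "samples"), showWarnings = FALSE)
  n <- n_samples(dataset)
  files <- sprintf("samples/sample_%05d.csv", seq_len(n))
  for (i in seq_len(n))
    write_recording(dataset$samples[[i]], file.path(dir, files[i]))
  manifest <- data.frame(
    file = files,
    label = dataset$info$label,
    subject = dataset$info$subject,
    seating = dataset$info$seating,
    length = vapply(dataset$samples, ncol, integer(1)),
    channels = vapply(dataset$samples, nrow, integer(1)),
    stringsAsFactors = FALSE)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(sampling_rate = dataset$sampling_rate),
                       file.path(dir, "meta.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_dataset
#' @export
load_dataset <- function(dir) {
  manifest_path <- file.path(dir, "manifest.csv")
  if (!file.exists(manifest_path))
    stop("no manifest.csv in ", dir)
  manifest <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  required <- c("file", "label", "subject", "seating", "length", "channels")
  missing_cols <- setdiff(required, names(manifest))
  if (length(missing_cols))
    stop("manifest is missing column(s): ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(manifest$file))
    stop("manifest lists duplicate file paths")
  meta_path <- file.path(dir, "meta.json")
  rate <- if (file.exists(meta_path))
    jsonlite::read_json(meta_path)$sampling_rate else 200
  problems <- character(0)
  samples <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    f <- file.path(dir, manifest$file[i])
    if (!file.exists(f)) {
      problems <- c(problems, paste0(manifest$file[i], ": missing"))
      next
    }
    s <- tryCatch(read_recording(f), error = function(e) conditionMessage(e))
    if (is.character(s)) {
      problems <- c(problems, paste0(manifest$file[i], ": ", s))
      next
    }
    if (ncol(s) != manifest$length[i] || nrow(s) != manifest$channels[i]) {
      problems <- c(problems,
                    paste0(manifest$file[i], ": shape ", nrow(s), "x", ncol(s),
                           " does not match manifest (", manifest$channels[i],
                           "x", manifest$length[i], ")"))
      next
    }
    samples[[i]] <- s
  }
  if (length(problems))
    stop("dataset validation failed:\n  ", paste(problems, collapse = "\n  "))
  gesture_dataset(samples, manifest$label, manifest$subject,
                  manifest$seating, sampling_rate = rate)
}
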