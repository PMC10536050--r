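#' Construct a continuous multichannel EEG recording
#'
#' The basic container for continuous data: a channels x samples signal
#' matrix in microvolts, named channels, a sampling rate, and an event table
#' of (onset_sample, code) pairs with 0-based sample indices.
#'
#' @param signal numeric matrix, channels in rows, samples in columns.
#' @param channel_names character vector, one unique name per row.
#' @param fs sampling rate in Hz.
#' @param events data.frame with integer columns `onset` (0-based sample
#'   index) and `code`, one row per event. Defaults to no events.
#' @param subject_id free-form subject identifier.
#' @return an object of class `eeg_raw`.
#' @export
raw_recording <- function(signal, channel_names, fs,
                          events = data.frame(onset = integer(),
                                              code = integer()),
                          subject_id = "") {
  signal <- as.matrix(signal)
  storage.mode(signal) <- "double"
  rec <- structure(
    list(signal = signal, channel_names = as.character(channel_names),
         fs = as.numeric(fs),
         events = data.frame(onset = as.integer(events$onset),
                             code = as.integer(events$code)),
         subject_id = as.character(subject_id)),
    class = "eeg_raw")
  validate_raw(rec)
  rec
}

validate_raw <- function(rec) {
  stopifnot(inherits(rec, "eeg_raw"))
  if (nrow(rec$signal) != length(rec$channel_names))
    stop("channel_names length (", length(rec$channel_names),
         ") does not match signal rows (", nrow(rec$signal), ")")
  if (anyDuplicated(rec$channel_names))
    stop("channel names must be unique")
  if (!is.finite(rec$fs) || rec$fs <= 0)
    stop("fs must be a positive number")
  n <- ncol(rec$signal)
  if (nrow(rec$events) > 0 &&
      (any(rec$events$onset < 0) || any(rec$events$onset >= n)))
    stop("event onsets must lie in [0, n_samples)")
  invisible(rec)
}

#' @export
print.eeg_raw <- function(x, ...) {
  cat(sprintf("<eeg_raw> %d channels x %d samples @ %g Hz, %d events%s\n",
              nrow(x$signal), ncol(x$signal), x$fs, nrow(x$events),
              if (nzchar(x$subject_id))
                paste0(", subject ", x$subject_id) else ""))
  invisible(x)
}

#' Construct a set of labelled trials (epochs)
#'
#' @param data numeric array `[n_trials x n_channels x n_samples]`.
#' @param labels integer class per trial, values in
#'   `0:(length(class_names)-1)`, or `NULL` when unlabelled.
#' @param fs sampling rate in Hz.
#' @param channel_names character vector of length `dim(data)[2]`.
#' @param class_names ordered class names; the default fixes the code
#'   mapping left=0, right=1, foot=2, tongue=3.
#' @return an object of class `eeg_epochs`.
#' @export
epoch_set <- function(data, labels, fs, channel_names,
                      class_names = c("left", "right", "foot", "tongue")) {
  data <- as.array(data)
  storage.mode(data) <- "double"
  e <- structure(
    list(data = data,
         labels = if (is.null(labels)) NULL else as.integer(labels),
         fs = as.numeric(fs), channel_names = as.character(channel_names),
         class_names = as.character(class_names)),
    class = "eeg_epochs")
  validate_epochs(e)
  e
}

validate_epochs <- function(e) {
  stopifnot(inherits(e, "eeg_epochs"))
  d <- dim(e$data)
  if (length(d) != 3)
    stop("epoch data must be a 3-d array [trials x channels x samples]")
  if (length(e$channel_names) != d[2])
    stop("channel_names length (", length(e$channel_names),
         ") does not match channel dimension (", d[2], ")")
  if (!is.null(e$labels)) {
    if (length(e$labels) != d[1])
      stop("labels length (", length(e$labels),
           ") does not match trial count (", d[1], ")")
    bad <- e$labels < 0 | e$labels >= length(e$class_names)
    if (any(bad)) stop("labels out of range for class_names")
  }
  if (!is.finite(e$fs) || e$fs <= 0) stop("fs must be positive")
  invisible(e)
}

#' @export
print.eeg_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<eeg_epochs> %d trials x %d channels x %d samples @ %g Hz%s\n",
              d[1], d[2], d[3], x$fs,
              if (is.null(x$labels)) " (unlabelled)" else ""))
  if (!is.null(x$labels))
    cat("  classes:", paste(sprintf("%s=%d", x$class_names,
                                    table(factor(x$labels,
                                                 0:(length(x$class_names) - 1)))),
                            collapse = ", "), "\n")
  invisible(x)
}

n_trials <- function(e) dim(e$data)[1]

#' Read a continuous EEG recording
#'
#' Supports GDF 2.x files (the BCI Competition IV-2a distribution format,
#' read-only) and the package's own single-file recording archive as written
#' by [write_raw()].
#'
#' @param path file to read.
#' @param format `"gdf"`, `"archive"`, or `"auto"` (sniff from the file
#'   magic).
#' @return an [raw_recording()] object.
#' @export
read_raw <- function(path, format = c("auto", "gdf", "archive")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    magic <- readBin(path, "raw", n = 3)
    format <- if (identical(rawToChar(magic), "GDF")) "gdf" else "archive"
  }
  if (format == "gdf") return(read_gdf(path))
  obj <- readRDS(path)
  if (!identical(obj$container, "clrnet_raw"))
    stop("not a clrnet recording archive: ", path)
  raw_recording(obj$signal, obj$channel_names, obj$fs, obj$events,
                obj$subject_id)
}

#' Write a recording to the internal archive format
#'
#' A lossless single-file container (named arrays, self-describing); reading
#' it back with [read_raw()] recovers a bit-identical recording.
#'
#' @param rec an `eeg_raw` recording.
#' @param path output file.
#' @export
write_raw <- function(rec, path) {
  validate_raw(rec)
  saveRDS(list(container = "clrnet_raw", version = 1L,
               signal = rec$signal, channel_names = rec$channel_names,
               fs = rec$fs, events = rec$events,
               subject_id = rec$subject_id),
          path)
  invisible(path)
}

#' Save / load an epoch set losslessly
#'
#' @param e an `eeg_epochs` object.
#' @param path archive file.
#' @export
save_epochs <- function(e, path) {
  validate_epochs(e)
  saveRDS(list(container = "clrnet_epochs", version = 1L,
               data = e$data, labels = e$labels, fs = e$fs,
               channel_names = e$channel_names, class_names = e$class_names),
          path)
  invisible(path)
}

#' @rdname save_epochs
#' @export
load_epochs <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  obj <- readRDS(path)
  if (!identical(obj$container, "clrnet_epochs"))
    stop("not a clrnet epoch archive: ", path)
  e <- epoch_set(obj$data, obj$labels, obj$fs, obj$channel_names,
                 obj$class_names)
  validate_epochs(e)
  e
}
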