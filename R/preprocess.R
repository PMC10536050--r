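# Preprocessing chain: zero-phase Butterworth band-pass on the continuous
# recording, EOG channel removal, cue-locked epoch extraction, wavelet-packet
# Mu/Beta reconstruction, optional channel selection.

#' Band-pass filter specification
#'
#' @param band `(lo, hi)` passband in Hz; default 8-30 Hz.
#' @param order Butterworth design order (default 4).
#' @param zero_phase apply forward-backward (`filtfilt`) for zero group
#'   delay (default `TRUE`).
#' @export
filter_spec <- function(band = c(8, 30), order = 4, zero_phase = TRUE) {
  if (band[1] <= 0 || band[2] <= band[1])
    stop("band must satisfy 0 < lo < hi")
  list(band = band, family = "butterworth", order = as.integer(order),
       zero_phase = isTRUE(zero_phase))
}

#' Band-pass filter a continuous recording
#'
#' Applies a Butterworth band-pass to every channel. With
#' `spec$zero_phase = TRUE` the filter is run forward and backward
#' (`signal::filtfilt`), doubling the attenuation and cancelling group delay
#' so rhythm timing is preserved.
#'
#' @param rec an `eeg_raw` recording.
#' @param spec a [filter_spec()].
#' @return a filtered recording; shape, names and events unchanged.
#' @export
bandpass <- function(rec, spec = filter_spec()) {
  validate_raw(rec)
  if (spec$band[2] >= rec$fs / 2)
    stop("band edge ", spec$band[2], " Hz >= Nyquist (", rec$fs / 2, " Hz)")
  bf <- signal::butter(spec$order, spec$band / (rec$fs / 2), type = "pass")
  out <- rec
  for (ch in seq_len(nrow(rec$signal))) {
    x <- rec$signal[ch, ]
    out$signal[ch, ] <- if (spec$zero_phase)
      signal::filtfilt(bf, x) else as.numeric(signal::filter(bf, x))
  }
  out
}

EOG_CHANNELS <- c("EOG-left", "EOG-central", "EOG-right")

#' Drop the EOG channels from a recording
#'
#' Ocular influence is handled by excluding the three EOG channels, leaving
#' the 22 EEG channels of a 25-channel IV-2a style recording. EEG rows are
#' untouched bit-for-bit and keep their order.
#'
#' @param rec an `eeg_raw` recording.
#' @param strict error if the EOG channels are absent (default `TRUE`);
#'   with `strict = FALSE` a recording already lacking them passes through
#'   unchanged.
#' @export
remove_eog <- function(rec, strict = TRUE) {
  validate_raw(rec)
  present <- EOG_CHANNELS %in% rec$channel_names
  if (!all(present)) {
    if (strict)
      stop("missing EOG channel(s) ",
           paste(EOG_CHANNELS[!present], collapse = ", "),
           "; channels found: ", paste(rec$channel_names, collapse = ", "))
    if (!any(present)) return(rec)
  }
  keep <- !(rec$channel_names %in% EOG_CHANNELS)
  out <- rec
  out$signal <- rec$signal[keep, , drop = FALSE]
  out$channel_names <- rec$channel_names[keep]
  out
}

# Map IV-2a cue annotation codes to class codes left=0 right=1 foot=2
# tongue=3; returns NULL when the codes are not class cues.
codes_to_labels <- function(codes) {
  if (all(codes %in% 769:772)) return(as.integer(codes - 769L))
  if (all(codes %in% 0:3)) return(as.integer(codes))
  NULL
}

#' Extract cue-locked trials from a continuous recording
#'
#' Cuts, for every trial-onset event, the window `window` (seconds, relative
#' to trial onset; default the 3-6 s imagery period) as one epoch of exactly
#' `round(diff(window) * fs)` samples, using the half-open sample interval
#' `[onset + round(window[1]*fs), +n)` with 0-based sample indexing. At
#' 250 Hz the default yields 750-sample epochs.
#'
#' @param rec an `eeg_raw` recording with trial-onset events.
#' @param window `(t0, t1)` in seconds relative to trial onset.
#' @param labels optional integer class labels (0-3) per trial, or a path to
#'   a side-car text file with one label per line; when omitted, labels are
#'   derived from the event codes if they use the 769-772 cue convention.
#' @return an `eeg_epochs` set.
#' @export
extract_epochs <- function(rec, window = c(3, 6), labels = NULL) {
  validate_raw(rec)
  onsets <- rec$events$onset
  if (length(onsets) == 0) stop("recording has no trial events")
  n_len <- round(diff(window) * rec$fs)
  starts <- onsets + round(window[1] * rec$fs)
  bad <- which(starts < 0 | starts + n_len > ncol(rec$signal))
  if (length(bad))
    stop("epoch window exceeds recording bounds for trial(s) ",
         paste(bad, collapse = ", "))
  if (is.character(labels)) labels <- as.integer(readLines(labels))
  if (is.null(labels)) labels <- codes_to_labels(rec$events$code)
  if (!is.null(labels) && length(labels) != length(onsets))
    stop("labels length (", length(labels),
         ") does not match trial count (", length(onsets), ")")
  data <- array(0, c(length(onsets), nrow(rec$signal), n_len))
  for (tr in seq_along(onsets))
    data[tr, , ] <- rec$signal[, (starts[tr] + 1):(starts[tr] + n_len)]
  epoch_set(data, labels, rec$fs, rec$channel_names)
}

#' Restrict an epoch set to named channels
#'
#' @param e an `eeg_epochs` set.
#' @param names channel names to keep, in the requested order.
#' @export
select_channels <- function(e, names) {
  validate_epochs(e)
  idx <- match(names, e$channel_names)
  if (anyNA(idx))
    stop("unknown channel(s): ", paste(names[is.na(idx)], collapse = ", "))
  epoch_set(e$data[, idx, , drop = FALSE], e$labels, e$fs,
            e$channel_names[idx], e$class_names)
}

#' Full preprocessing pipeline
#'
#' Composition band-pass -> EOG removal -> epoch extraction -> wavelet-packet
#' Mu/Beta reconstruction (-> optional channel selection). With the defaults
#' a simulated 25-channel, 288-trial subject at 250 Hz becomes a
#' `288 x 22 x 240` epoch set.
#'
#' @param rec an `eeg_raw` recording.
#' @param filter a [filter_spec()].
#' @param window epoching window in seconds relative to trial onset.
#' @param wpd a [wpd_config()].
#' @param channels optional channel names to keep after reconstruction.
#' @param labels optional per-trial labels (see [extract_epochs()]).
#' @return an `eeg_epochs` set ready for the network.
#' @export
preprocess_pipeline <- function(rec, filter = filter_spec(),
                                window = c(3, 6), wpd = wpd_config(),
                                channels = NULL, labels = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("preprocess stage '", name, "': ", conditionMessage(e),
           call. = FALSE))
  }
  rec <- stage("bandpass", bandpass(rec, filter))
  rec <- stage("remove_eog", remove_eog(rec))
  e <- stage("extract_epochs", extract_epochs(rec, window, labels))
  e <- stage("wpd_reconstruct", wpd_reconstruct(e, wpd))
  if (!is.null(channels)) e <- stage("select_channels",
                                     select_channels(e, channels))
  e
}
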