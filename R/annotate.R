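## QRS-count window annotation: label each fixed window apnea ("A") when it
## contains fewer QRS complexes than a threshold, else normal ("N").
## Bradycardic minutes — fewer beats — are the annotation's apnea proxy.
##
## The number of windows is derived from the signal extent in samples
## (extent %/% window_size), supplied explicitly from the record length (or
## max beat index + 1); windows are half-open [start, start + window_size),
## so a beat exactly at a window start belongs to that window.

#' Annotation parameters
#'
#' @param sampling_rate_hz Positive sampling rate in Hz.
#' @param qrs_threshold Positive integer: windows with a QRS count strictly
#'   below this are labelled apnea. There is no universal value; choose it
#'   between the expected per-window beat counts of the two regimes (the
#'   synthetic simulator's defaults admit any threshold in (55, 65), e.g. 60).
#' @param signal_extent_samples Total signal extent in samples; must cover at
#'   least one window.
#' @param time_window_s Window duration in seconds (default 60).
#' @return An object of class `annotation_params` with the derived
#'   `window_size_samples = round(time_window_s * sampling_rate_hz)`.
#' @export
annotation_params <- function(sampling_rate_hz, qrs_threshold,
                              signal_extent_samples, time_window_s = 60) {
  if (sampling_rate_hz <= 0) abort_param("sampling_rate_hz must be positive")
  if (time_window_s <= 0) abort_param("time_window_s must be positive")
  qrs_threshold <- as.integer(qrs_threshold)
  if (is.na(qrs_threshold) || qrs_threshold < 1L)
    abort_param("qrs_threshold must be a positive integer")
  w <- as.integer(round(time_window_s * sampling_rate_hz))
  signal_extent_samples <- as.numeric(signal_extent_samples)
  if (signal_extent_samples < w)
    abort_degenerate("signal extent shorter than one window")
  structure(list(sampling_rate_hz = sampling_rate_hz,
                 time_window_s = time_window_s,
                 qrs_threshold = qrs_threshold,
                 window_size_samples = w,
                 signal_extent_samples = signal_extent_samples),
            class = "annotation_params")
}

#' Annotate windows as apnea/normal from QRS counts
#'
#' For each of `floor(signal_extent_samples / window_size_samples)` windows,
#' counts the QRS indices falling in the half-open interval
#' `[i * w, (i + 1) * w)` and labels the window `"A"` when the count is
#' strictly below `qrs_threshold`, `"N"` otherwise.
#'
#' @param qrs A [qrs_track()] whose indices all lie below
#'   `signal_extent_samples`.
#' @param params An [annotation_params()].
#' @return An [apnea_track()] with one entry per window, ordered by start.
#' @examples
#' q <- qrs_track("r1", seq(0, 11900, by = 100))
#' p <- annotation_params(100, qrs_threshold = 30,
#'                        signal_extent_samples = 12000)
#' annotate_by_qrs_count(q, p)$labels  # both minutes hold 60 beats -> "N"
#' @export
annotate_by_qrs_count <- function(qrs, params) {
  stopifnot(inherits(qrs, "qrs_track"), inherits(params, "annotation_params"))
  w <- params$window_size_samples
  idx <- qrs$sample_indices
  if (length(idx) && max(idx) >= params$signal_extent_samples)
    abort_consistency("QRS index at or beyond signal extent")
  n_win <- as.integer(params$signal_extent_samples %/% w)
  if (n_win < 1L) abort_degenerate("zero windows in extent")
  idx <- idx[idx < n_win * w]       # beats in a trailing partial window are dropped with it
  counts <- tabulate(idx %/% w + 1L, nbins = n_win)
  labels <- ifelse(counts < params$qrs_threshold, "A", "N")
  apnea_track(qrs$record_id, labels, (seq_len(n_win) - 1) * w, w)
}

#' Convert an apnea label track to binary training targets
#'
#' `"A"` maps to 1 (apnea), `"N"` to 0, order preserved.
#'
#' @param track An [apnea_track()].
#' @return Numeric 0/1 vector, one element per window.
#' @export
labels_to_targets <- function(track) {
  stopifnot(inherits(track, "apnea_track"))
  as.numeric(track$labels == "A")
}

#' Attach track labels to matching segments
#'
#' Each segment receives the label of the track entry with the same record
#' id and start sample; segments with no matching entry are dropped and the
#' number dropped is stored in attribute `n_dropped`.
#'
#' @param track An [apnea_track()] whose `window_size_samples` equals the
#'   segment length.
#' @param segs A [segment_set()].
#' @return A labelled [segment_set()] with attribute `n_dropped`.
#' @export
align_targets_to_segments <- function(track, segs) {
  stopifnot(inherits(track, "apnea_track"), inherits(segs, "segment_set"))
  if (track$window_size_samples != segs$segment_len)
    abort_consistency(sprintf(
      "window size mismatch: track %d vs segments %d",
      as.integer(track$window_size_samples), segs$segment_len))
  key <- paste(track$record_id, track$start_samples)
  seg_key <- paste(segs$provenance$record_id, segs$provenance$start_sample)
  pos <- match(seg_key, key)
  keep <- !is.na(pos)
  out <- subset_segments(segs, which(keep))
  out$labels <- as.numeric(track$labels[pos[keep]] == "A")
  attr(out, "n_dropped") <- sum(!keep)
  out
}
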