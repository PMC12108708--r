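## Signal conditioning: zero-phase Butterworth bandpass, moving-average
## smoothing (diagnostic), robust outlier flagging, fixed-window
## segmentation and per-segment z-score normalization.
##
## The default classification chain is filter -> segment -> normalize;
## smoothing is a visualization aid and outliers are flagged, not removed.

#' Bandpass filter specification
#'
#' Pass band for ECG conditioning. The defaults (0.5--45 Hz) keep the QRS
#' energy while removing baseline drift and high-frequency noise. The filter
#' is a Butterworth design of the given order applied as a high-pass /
#' low-pass cascade; with `zero_phase = TRUE` each stage runs
#' forward-backward so no group delay is introduced (QRS timing preserved).
#'
#' @param low_hz Lower band edge in Hz (default 0.5).
#' @param high_hz Upper band edge in Hz (default 45).
#' @param order Filter order per stage (default 4).
#' @param zero_phase Apply forward-backward (default `TRUE`).
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(low_hz = 0.5, high_hz = 45, order = 4L,
                        zero_phase = TRUE) {
  if (low_hz <= 0 || high_hz <= low_hz)
    abort_param("need 0 < low_hz < high_hz")
  if (order < 1L) abort_param("order must be a positive integer")
  structure(list(low_hz = low_hz, high_hz = high_hz,
                 order = as.integer(order), zero_phase = isTRUE(zero_phase)),
            class = "filter_spec")
}

#' Bandpass-filter an ECG record
#'
#' @param record An [ecg_record()].
#' @param spec A [filter_spec()]; `high_hz` must be below the Nyquist
#'   frequency of the record.
#' @return A filtered [ecg_record()] of identical length and sampling rate.
#' @export
bandpass_filter <- function(record, spec = filter_spec()) {
  stopifnot(inherits(record, "ecg_record"))
  nyq <- record$sampling_rate_hz / 2
  if (spec$high_hz >= nyq)
    abort_param(sprintf("high_hz (%g) must be below Nyquist (%g)",
                        spec$high_hz, nyq))
  if (record$n_samples < 3L * spec$order)
    abort_degenerate("signal shorter than 3 x filter order")
  hp <- signal::butter(spec$order, spec$low_hz / nyq, type = "high")
  lp <- signal::butter(spec$order, spec$high_hz / nyq, type = "low")
  x <- record$samples
  if (spec$zero_phase) {
    x <- signal::filtfilt(hp, x)
    x <- signal::filtfilt(lp, x)
  } else {
    x <- as.numeric(signal::filter(hp, x))
    x <- as.numeric(signal::filter(lp, x))
  }
  ecg_record(record$record_id, record$sampling_rate_hz, x)
}

#' Moving-average smoothing
#'
#' Centered moving average of odd window length; edge samples are averaged
#' over the available (truncated) window so output length is unchanged. This
#' is a diagnostic view of the signal and is not part of the default
#' classification chain.
#'
#' @param record An [ecg_record()].
#' @param window_len Positive odd integer window length, at most `n_samples`.
#' @return A smoothed [ecg_record()].
#' @export
smooth_signal <- function(record, window_len = 5L) {
  stopifnot(inherits(record, "ecg_record"))
  window_len <- as.integer(window_len)
  if (is.na(window_len) || window_len < 1L || window_len %% 2L == 0L)
    abort_param("window_len must be a positive odd integer")
  if (window_len > record$n_samples)
    abort_param("window_len exceeds signal length")
  x <- record$samples
  n <- length(x)
  h <- (window_len - 1L) %/% 2L
  cs <- c(0, cumsum(x))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  y <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  ecg_record(record$record_id, record$sampling_rate_hz, y)
}

#' Flag amplitude outliers with a robust median/MAD rule
#'
#' A sample is flagged when its absolute deviation from the signal median
#' exceeds `k` times the MAD (scaled by 1.4826 so it estimates the standard
#' deviation under normality). When the MAD is zero the rule is degenerate:
#' an empty index set is returned with attribute `degenerate = TRUE`.
#' Outliers are reported, never removed, by this function.
#'
#' @param record An [ecg_record()] with at least 3 samples.
#' @param k Positive multiplier (default 5).
#' @return 0-based integer vector of flagged sample indices, with attribute
#'   `degenerate`.
#' @export
detect_outliers <- function(record, k = 5) {
  stopifnot(inherits(record, "ecg_record"))
  if (record$n_samples < 3L) abort_param("need at least 3 samples")
  if (k <= 0) abort_param("k must be positive")
  x <- record$samples
  med <- stats::median(x)
  madv <- stats::mad(x, constant = 1.4826)
  if (madv == 0) {
    out <- integer(0)
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  out <- which(abs(x - med) > k * madv) - 1L
  attr(out, "degenerate") <- FALSE
  out
}

#' Construct a segment set
#'
#' Internal-facing constructor for the container holding fixed-length
#' segments, optional binary labels (1 = apnea) and per-segment provenance.
#'
#' @param segments Numeric matrix, one segment per row.
#' @param provenance Data frame with columns `record_id` and `start_sample`
#'   (0-based), one row per segment.
#' @param labels Optional numeric 0/1 vector aligned with rows.
#' @param normalized Whether rows are per-segment z-scored.
#' @param partition Optional partition tag: `"training"`, `"validation"` or
#'   `"test"`; used by the leakage guards.
#' @return An object of class `segment_set`.
#' @export
segment_set <- function(segments, provenance, labels = NULL,
                        normalized = FALSE, partition = NULL) {
  segments <- as.matrix(segments)
  if (!is.data.frame(provenance) ||
      !all(c("record_id", "start_sample") %in% names(provenance)) ||
      nrow(provenance) != nrow(segments))
    abort_param("provenance must align 1:1 with segment rows")
  if (!is.null(labels)) {
    labels <- as.numeric(labels)
    if (length(labels) != nrow(segments))
      abort_param("labels must align 1:1 with segment rows")
    if (length(labels) && !all(labels %in% c(0, 1)))
      abort_param("labels must be binary (1 = apnea)")
  }
  structure(list(segments = segments,
                 labels = labels,
                 provenance = provenance[, c("record_id", "start_sample")],
                 normalized = isTRUE(normalized),
                 segment_len = ncol(segments),
                 partition = partition),
            class = "segment_set")
}

#' @export
print.segment_set <- function(x, ...) {
  cat(sprintf("<segment_set: %d segments x %d samples%s%s%s>\n",
              nrow(x$segments), x$segment_len,
              if (x$normalized) ", normalized" else "",
              if (!is.null(x$labels))
                sprintf(", %d apnea / %d normal", sum(x$labels == 1),
                        sum(x$labels == 0)) else ", unlabeled",
              if (!is.null(x$partition)) paste0(", partition=", x$partition)
              else ""))
  invisible(x)
}

#' Cut a record into fixed windows and normalize each
#'
#' Splits the record into `floor(n_samples / window_size)` non-overlapping
#' windows of `window_size = round(window_s * sampling_rate_hz)` samples
#' (default one minute); the trailing partial window is dropped. With
#' `normalize = TRUE` each window is independently z-scored (constant
#' windows map to all-zeros).
#'
#' @param record An [ecg_record()] at least one window long.
#' @param window_s Window duration in seconds (default 60).
#' @param normalize Z-score each row (default `TRUE`).
#' @return A [segment_set()] with provenance starts `0, w, 2w, ...`.
#' @export
segment_and_normalize <- function(record, window_s = 60, normalize = TRUE) {
  stopifnot(inherits(record, "ecg_record"))
  w <- as.integer(round(window_s * record$sampling_rate_hz))
  if (w < 1L) abort_param("window shorter than one sample")
  n_seg <- record$n_samples %/% w
  if (n_seg < 1L) abort_degenerate("record shorter than one window")
  m <- matrix(record$samples[seq_len(n_seg * w)], nrow = n_seg, ncol = w,
              byrow = TRUE)
  if (normalize) m <- normalize_rows(m)
  segment_set(m,
              provenance = data.frame(
                record_id = rep(record$record_id, n_seg),
                start_sample = (seq_len(n_seg) - 1) * w,
                stringsAsFactors = FALSE),
              normalized = normalize)
}

## Row-wise z-score with the constant-row -> zeros guard. Uses the sample
## (n-1) standard deviation so rows satisfy sd == 1 exactly.
normalize_rows <- function(m) {
  mu <- rowMeans(m)
  ctr <- m - mu
  sdv <- sqrt(rowSums(ctr^2) / (ncol(m) - 1L))
  sdv_safe <- ifelse(sdv > 0, sdv, 1)
  out <- ctr / sdv_safe
  out[sdv == 0, ] <- 0
  out
}

#' Combine several segment sets into one
#'
#' Rows are stacked in order; all inputs must share the segment length,
#' normalization state and (if any) labelling.
#'
#' @param sets List of [segment_set()] objects.
#' @param partition Optional partition tag for the combined set.
#' @return A [segment_set()].
#' @export
bind_segment_sets <- function(sets, partition = NULL) {
  stopifnot(length(sets) >= 1L)
  lens <- vapply(sets, `[[`, 0L, "segment_len")
  if (length(unique(lens)) != 1L)
    abort_consistency("segment lengths differ across sets")
  norm <- vapply(sets, `[[`, FALSE, "normalized")
  if (length(unique(norm)) != 1L)
    abort_consistency("normalization state differs across sets")
  has_lab <- vapply(sets, function(s) !is.null(s$labels), FALSE)
  if (!all(has_lab) && any(has_lab))
    abort_consistency("cannot mix labeled and unlabeled sets")
  segment_set(do.call(rbind, lapply(sets, `[[`, "segments")),
              provenance = do.call(rbind, lapply(sets, `[[`, "provenance")),
              labels = if (all(has_lab))
                unlist(lapply(sets, `[[`, "labels")) else NULL,
              normalized = norm[[1L]],
              partition = partition)
}

#' Subset a segment set by row index
#'
#' @param segs A [segment_set()].
#' @param idx Integer row indices to keep.
#' @param partition Optional partition tag for the result.
#' @return A [segment_set()].
#' @export
subset_segments <- function(segs, idx, partition = segs$partition) {
  segment_set(segs$segments[idx, , drop = FALSE],
              provenance = segs$provenance[idx, , drop = FALSE],
              labels = if (!is.null(segs$labels)) segs$labels[idx] else NULL,
              normalized = segs$normalized,
              partition = partition)
}
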