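## Domain containers and text/CSV readers-writers for single-lead ECG data:
## sampled records, QRS annotation tracks (beat sample indices) and
## minute-wise apnea label tracks. Sample indexing is 0-based throughout and
## windows are half-open [start, start + window_size).

#' Construct a single-lead ECG record
#'
#' The basic container for one channel of sampled ECG: an identifier, the
#' sampling rate and the amplitude vector (millivolts).
#'
#' @param record_id Short string identifying the record (e.g. `"x01"`).
#' @param sampling_rate_hz Positive sampling rate in Hz (the apnea database
#'   convention is 100 Hz).
#' @param samples Numeric vector of finite amplitudes in millivolts.
#' @return An object of class `ecg_record` with fields `record_id`,
#'   `sampling_rate_hz`, `samples` and `n_samples`.
#' @examples
#' r <- ecg_record("x01", 100, sin(seq(0, 2 * pi, length.out = 200)))
#' r$n_samples
#' @export
ecg_record <- function(record_id, sampling_rate_hz, samples) {
  if (!is.character(record_id) || length(record_id) != 1L || !nzchar(record_id))
    abort_param("record_id must be a non-empty string")
  sampling_rate_hz <- as.numeric(sampling_rate_hz)
  if (length(sampling_rate_hz) != 1L || !is.finite(sampling_rate_hz) ||
      sampling_rate_hz <= 0)
    abort_param("sampling_rate_hz must be a single positive number")
  samples <- as.numeric(samples)
  if (anyNA(samples) || any(!is.finite(samples)))
    abort_param("all samples must be finite")
  structure(
    list(record_id = record_id,
         sampling_rate_hz = sampling_rate_hz,
         samples = samples,
         n_samples = length(samples)),
    class = "ecg_record")
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record '%s': %d samples @ %g Hz (%.1f s)>\n",
              x$record_id, x$n_samples, x$sampling_rate_hz,
              x$n_samples / x$sampling_rate_hz))
  invisible(x)
}

#' Construct a QRS annotation track
#'
#' Holds the 0-based sample indices of detected QRS complexes (heartbeats)
#' for one record; indices must be strictly increasing.
#'
#' @param record_id Record identifier the track belongs to.
#' @param sample_indices Strictly increasing non-negative integer vector of
#'   0-based beat sample indices.
#' @return An object of class `qrs_track`.
#' @export
qrs_track <- function(record_id, sample_indices) {
  idx <- as.numeric(sample_indices)
  if (anyNA(idx)) abort_param("QRS sample indices must not be NA")
  if (any(idx < 0)) abort_format("QRS sample indices must be non-negative")
  if (length(idx) > 1L && any(diff(idx) <= 0))
    abort_format("QRS sample indices must be strictly increasing")
  structure(list(record_id = record_id, sample_indices = idx),
            class = "qrs_track")
}

#' @export
print.qrs_track <- function(x, ...) {
  cat(sprintf("<qrs_track '%s': %d beats>\n", x$record_id,
              length(x$sample_indices)))
  invisible(x)
}

#' Construct a minute-wise apnea label track
#'
#' Per-window apnea ("A") / normal ("N") labels with their window start
#' samples. Starts must be strictly increasing multiples of the window size.
#'
#' @param record_id Record identifier.
#' @param labels Character vector over the alphabet `{"A", "N"}`.
#' @param start_samples 0-based window start samples, strictly increasing,
#'   each a multiple of `window_size_samples`.
#' @param window_size_samples Positive integer window length in samples.
#' @return An object of class `apnea_track`.
#' @export
apnea_track <- function(record_id, labels, start_samples, window_size_samples) {
  labels <- as.character(labels)
  if (length(labels) && !all(labels %in% c("A", "N")))
    abort_format("apnea labels must be 'A' or 'N'")
  start_samples <- as.numeric(start_samples)
  if (length(start_samples) != length(labels))
    abort_param("labels and start_samples must have equal length")
  window_size_samples <- as.numeric(window_size_samples)
  if (length(window_size_samples) != 1L || window_size_samples <= 0)
    abort_param("window_size_samples must be a single positive integer")
  if (length(start_samples) > 1L && any(diff(start_samples) <= 0))
    abort_format("window start samples must be strictly increasing")
  if (length(start_samples) && any(start_samples %% window_size_samples != 0))
    abort_format("window starts must be multiples of window_size_samples")
  structure(
    list(record_id = record_id, labels = labels,
         start_samples = start_samples,
         window_size_samples = window_size_samples),
    class = "apnea_track")
}

#' @export
print.apnea_track <- function(x, ...) {
  cat(sprintf("<apnea_track '%s': %d windows (%d apnea), window %d samples>\n",
              x$record_id, length(x$labels), sum(x$labels == "A"),
              as.integer(x$window_size_samples)))
  invisible(x)
}

## ---------------------------------------------------------------- records --

#' Read a single-lead ECG record
#'
#' Two dialects are supported: `"csv"` (a one-line header
#' `record_id,sampling_rate_hz` followed by one amplitude per line — the
#' canonical plain-text fixture format) and `"wfdb"` (a PhysioNet-style
#' header/signal pair, see [read_wfdb_record()]).
#'
#' @param path File path; for the WFDB dialect either the `.hea` file or the
#'   record base name.
#' @param dialect `"csv"` or `"wfdb"`.
#' @return An [ecg_record()].
#' @export
read_record <- function(path, dialect = c("csv", "wfdb")) {
  dialect <- match.arg(dialect)
  if (dialect == "wfdb") return(read_wfdb_record(path))
  if (!file.exists(path)) abort_io(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) abort_format(sprintf("%s: empty file", path))
  head_fields <- strsplit(trimws(lines[[1L]]), ",")[[1L]]
  if (length(head_fields) != 2L)
    abort_format(sprintf("%s: line 1: expected 'record_id,sampling_rate_hz'",
                         path))
  fs <- suppressWarnings(as.numeric(head_fields[[2L]]))
  if (is.na(fs) || fs <= 0)
    abort_format(sprintf("%s: line 1: non-positive or non-numeric sampling rate",
                         path))
  body <- lines[-1L]
  body <- body[nzchar(trimws(body))]
  if (length(body) == 0L)
    abort_format(sprintf("%s: empty signal (header only)", path))
  vals <- suppressWarnings(as.numeric(body))
  if (anyNA(vals)) {
    bad <- which(is.na(vals))[[1L]]
    abort_format(sprintf("%s: line %d: non-numeric amplitude '%s'",
                         path, bad + 1L, body[[bad]]))
  }
  ecg_record(head_fields[[1L]], fs, vals)
}

#' Write a single-lead ECG record
#'
#' @param record An [ecg_record()].
#' @param path Output path (for `"wfdb"`, the record base name; `.hea` and
#'   `.dat` are written beside it).
#' @param dialect `"csv"` or `"wfdb"`.
#' @return `path`, invisibly.
#' @export
write_record <- function(record, path, dialect = c("csv", "wfdb")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(record, "ecg_record"))
  if (dialect == "wfdb") return(write_wfdb_record(record, path))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%s,%.12g", record$record_id, record$sampling_rate_hz),
             con)
  writeLines(sprintf("%.12g", record$samples), con)
  invisible(path)
}

## ------------------------------------------------------------- QRS tracks --

#' Read a QRS annotation track
#'
#' The `"text"` dialect is one 0-based integer sample index per line. The
#' `"wfdb_ann"` dialect is the binary MIT annotation format (see
#' [read_wfdb_annotations()]). Duplicate consecutive indices are collapsed to
#' one; the number collapsed is reported via a warning and stored in the
#' `"n_duplicates"` attribute. Decreasing indices are a format error (the
#' machine-generated QRS files of the apnea database are known to contain
#' errors; only duplicate collapse is attempted here).
#'
#' @param path File path.
#' @param dialect `"text"` or `"wfdb_ann"`.
#' @param record_id Identifier to attach; defaults to the file base name.
#' @return A [qrs_track()] with attribute `n_duplicates`.
#' @export
read_qrs_track <- function(path, dialect = c("text", "wfdb_ann"),
                           record_id = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort_io(sprintf("file not found: %s", path))
  rid <- record_id %||% sub("\\.[^.]*$", "", basename(path))
  if (dialect == "wfdb_ann") {
    ann <- read_wfdb_annotations(path)
    idx <- ann$sample[ann$label == "N"]
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    idx <- suppressWarnings(as.numeric(lines))
    if (anyNA(idx)) {
      bad <- which(is.na(idx))[[1L]]
      abort_format(sprintf("%s: line %d: non-integer index '%s'",
                           path, bad, lines[[bad]]))
    }
  }
  if (any(idx < 0)) abort_format(sprintf("%s: negative sample index", path))
  dup <- 0L
  if (length(idx) > 1L) {
    d <- diff(idx)
    if (any(d < 0))
      abort_format(sprintf("%s: non-increasing sample indices", path))
    dup <- sum(d == 0)
    if (dup > 0L) {
      warning(sprintf("%s: collapsed %d duplicate QRS indices", path, dup),
              call. = FALSE)
      idx <- idx[c(TRUE, d > 0)]
    }
  }
  out <- qrs_track(rid, idx)
  attr(out, "n_duplicates") <- as.integer(dup)
  out
}

#' Write a QRS annotation track
#'
#' @param track A [qrs_track()].
#' @param path Output path.
#' @param dialect `"text"` (one index per line) or `"wfdb_ann"` (binary MIT
#'   annotation format, beat code `N`).
#' @return `path`, invisibly.
#' @export
write_qrs_track <- function(track, path, dialect = c("text", "wfdb_ann")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(track, "qrs_track"))
  if (dialect == "wfdb_ann") {
    write_wfdb_annotations(track$sample_indices,
                           rep("N", length(track$sample_indices)), path)
  } else {
    writeLines(sprintf("%d", as.integer(track$sample_indices)), path)
  }
  invisible(path)
}

## ----------------------------------------------------------- apnea tracks --

#' Read a minute-wise apnea label track
#'
#' The `"apn_text"` dialect is one character (`A` or `N`) per line, line i
#' labelling window i (0-based); the `"csv"` dialect has a `minute,label`
#' header. Window i starts at sample `i * round(window_s * sampling_rate_hz)`.
#' The `"wfdb_ann"` dialect reads the binary MIT annotation format.
#'
#' @param path File path.
#' @param dialect `"apn_text"`, `"csv"` or `"wfdb_ann"`.
#' @param sampling_rate_hz Sampling rate used to convert windows to samples.
#' @param window_s Window duration in seconds (default 60, i.e. one minute).
#' @param record_id Identifier to attach; defaults to the file base name.
#' @return An [apnea_track()].
#' @export
read_apnea_track <- function(path, dialect = c("apn_text", "csv", "wfdb_ann"),
                             sampling_rate_hz = 100, window_s = 60,
                             record_id = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort_io(sprintf("file not found: %s", path))
  rid <- record_id %||% sub("\\.[^.]*$", "", basename(path))
  w <- round(window_s * sampling_rate_hz)
  if (dialect == "wfdb_ann") {
    ann <- read_wfdb_annotations(path)
    return(apnea_track(rid, ann$label, ann$sample, w))
  }
  lines <- readLines(path, warn = FALSE)
  if (dialect == "csv" && length(lines)) lines <- lines[-1L]
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(apnea_track(rid, character(), numeric(), w))
  labels <- character(length(lines))
  for (i in seq_along(lines)) {
    lab <- trimws(lines[[i]])
    if (dialect == "csv") {
      fields <- strsplit(lab, ",")[[1L]]
      if (length(fields) != 2L)
        abort_format(sprintf("%s: line %d: expected 'minute,label'", path,
                             i + 1L))
      lab <- trimws(fields[[2L]])
    }
    if (!lab %in% c("A", "N"))
      abort_format(sprintf("%s: line %d: label '%s' not in {A, N}",
                           path, i + if (dialect == "csv") 1L else 0L, lab))
    labels[[i]] <- lab
  }
  apnea_track(rid, labels, (seq_along(labels) - 1) * w, w)
}

#' Write a minute-wise apnea label track
#'
#' @param track An [apnea_track()].
#' @param path Output path.
#' @param dialect `"apn_text"`, `"csv"` or `"wfdb_ann"`.
#' @return `path`, invisibly.
#' @export
write_apnea_track <- function(track, path,
                              dialect = c("apn_text", "csv", "wfdb_ann")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(track, "apnea_track"))
  if (dialect == "wfdb_ann") {
    write_wfdb_annotations(track$start_samples, track$labels, path)
  } else if (dialect == "csv") {
    writeLines(c("minute,label",
                 sprintf("%d,%s",
                         as.integer(track$start_samples /
                                      track$window_size_samples),
                         track$labels)), path)
  } else {
    writeLines(track$labels, path)
  }
  invisible(path)
}

## ---------------------------------------------------------------- dataset --

#' Write a dataset of records with their annotation tracks
#'
#' Writes every record, QRS track and apnea track to `directory` in the
#' chosen dialect and a `manifest.json` listing each file with its record id
#' and role. Record ids must be consistent across the three collections.
#'
#' @param records List of [ecg_record()] objects.
#' @param qrs_tracks List of [qrs_track()] objects (same record ids).
#' @param apnea_tracks List of [apnea_track()] objects (same record ids).
#' @param directory Output directory (created if needed).
#' @param dialect `"csv"` (text dialects throughout) or `"wfdb"` (binary
#'   header/signal pairs and MIT annotation files).
#' @return The manifest as a data frame (`record_id`, `role`, `file`),
#'   invisibly the same as written to `manifest.json`.
#' @export
write_dataset <- function(records, qrs_tracks, apnea_tracks, directory,
                          dialect = c("csv", "wfdb")) {
  dialect <- match.arg(dialect)
  ids <- vapply(records, `[[`, "", "record_id")
  qid <- vapply(qrs_tracks, `[[`, "", "record_id")
  aid <- vapply(apnea_tracks, `[[`, "", "record_id")
  if (!identical(sort(ids), sort(qid)) || !identical(sort(ids), sort(aid)))
    abort_consistency("record_ids differ across records/qrs/apnea collections")
  if (!dir.exists(directory) &&
      !dir.create(directory, recursive = TRUE, showWarnings = FALSE))
    abort_io(sprintf("cannot create directory %s", directory))
  rows <- list()
  for (r in records) {
    id <- r$record_id
    q <- qrs_tracks[[which(qid == id)[[1L]]]]
    a <- apnea_tracks[[which(aid == id)[[1L]]]]
    if (dialect == "wfdb") {
      sig <- file.path(directory, id)
      write_record(r, sig, "wfdb")
      sig_file <- paste0(id, ".hea")
      qf <- file.path(directory, paste0(id, ".qrs"))
      write_qrs_track(q, qf, "wfdb_ann")
      af <- file.path(directory, paste0(id, ".apn"))
      write_apnea_track(a, af, "wfdb_ann")
    } else {
      sig_file <- paste0(id, ".ecg.csv")
      write_record(r, file.path(directory, sig_file), "csv")
      qf <- file.path(directory, paste0(id, ".qrs.txt"))
      write_qrs_track(q, qf, "text")
      af <- file.path(directory, paste0(id, ".apn.txt"))
      write_apnea_track(a, af, "apn_text")
    }
    rows[[length(rows) + 1L]] <- data.frame(
      record_id = id,
      role = c("signal", "qrs", "apnea"),
      file = c(sig_file, basename(qf), basename(af)),
      stringsAsFactors = FALSE)
  }
  manifest <- if (length(rows)) do.call(rbind, rows) else
    data.frame(record_id = character(), role = character(),
               file = character(), stringsAsFactors = FALSE)
  meta <- list(dialect = dialect,
               sampling_rate_hz = if (length(records))
                 records[[1L]]$sampling_rate_hz else NA,
               files = manifest)
  jsonlite::write_json(meta, file.path(directory, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Read back a dataset written by [write_dataset()]
#'
#' @param directory Directory containing `manifest.json`.
#' @return List with elements `records`, `qrs_tracks`, `apnea_tracks` (each a
#'   named list keyed by record id) and `manifest`.
#' @export
read_dataset <- function(directory) {
  mf <- file.path(directory, "manifest.json")
  if (!file.exists(mf)) abort_io(sprintf("no manifest.json in %s", directory))
  meta <- jsonlite::read_json(mf, simplifyVector = TRUE)
  manifest <- meta$files
  records <- list(); qrs <- list(); apn <- list()
  fs <- meta$sampling_rate_hz
  if (is.data.frame(manifest) && nrow(manifest)) {
    for (i in seq_len(nrow(manifest))) {
      id <- manifest$record_id[[i]]
      f <- file.path(directory, manifest$file[[i]])
      role <- manifest$role[[i]]
      if (role == "signal") {
        records[[id]] <- read_record(f, if (meta$dialect == "wfdb") "wfdb"
                                     else "csv")
      } else if (role == "qrs") {
        qrs[[id]] <- read_qrs_track(f, if (meta$dialect == "wfdb") "wfdb_ann"
                                    else "text", record_id = id)
      } else {
        apn[[id]] <- read_apnea_track(f, if (meta$dialect == "wfdb") "wfdb_ann"
                                      else "apn_text",
                                      sampling_rate_hz = fs, record_id = id)
      }
    }
  }
  ## consistency: annotation indices must lie inside the signal
  for (id in names(records)) {
    if (!is.null(qrs[[id]]) &&
        length(qrs[[id]]$sample_indices) &&
        max(qrs[[id]]$sample_indices) >= records[[id]]$n_samples)
      warning(sprintf("record %s: QRS indices beyond signal extent", id),
              call. = FALSE)
  }
  list(records = records, qrs_tracks = qrs, apnea_tracks = apn,
       manifest = manifest)
}
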