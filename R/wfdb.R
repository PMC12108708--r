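## Minimal reader/writer for the PhysioNet WFDB dialect used by the apnea
## database: a text header (.hea) plus a format-16 signal file (.dat,
## little-endian int16, physical value = (adu - baseline) / gain), and the
## MIT 2-byte annotation format (.qrs/.apn) with the SKIP long-interval
## extension. Only the single-signal subset needed here is supported; the
## codec is deliberately small and is exercised by round-trip tests.
##
## Amplitudes in the binary dialect are quantized to 1/gain millivolts
## (default gain 200 adu/mV, the apnea database's own setting), so binary
## round-trips reproduce amplitudes to half a quantization step, not to
## floating-point precision as the text dialects do.

WFDB_DEFAULT_GAIN <- 200

## MIT annotation type codes for the two mnemonics the apnea database uses:
## 'N' (code 1) for beats / normal minutes, 'A' (code 8) for apnea minutes.
ANN_CODE <- c(N = 1L, A = 8L)
ANN_SKIP <- 59L

read_wfdb_record <- function(path) {
  hea <- if (grepl("\\.hea$", path)) path else paste0(path, ".hea")
  if (!file.exists(hea)) abort_io(sprintf("file not found: %s", hea))
  lines <- readLines(hea, warn = FALSE)
  lines <- lines[!grepl("^#", lines)]
  if (length(lines) < 2L) abort_format(sprintf("%s: truncated header", hea))
  rec <- strsplit(trimws(lines[[1L]]), "\\s+")[[1L]]
  if (length(rec) < 4L)
    abort_format(sprintf("%s: record line needs id nsig fs nsamples", hea))
  record_id <- rec[[1L]]
  nsig <- as.integer(rec[[2L]])
  if (is.na(nsig) || nsig != 1L)
    abort_format(sprintf("%s: only single-signal records supported", hea))
  fs <- as.numeric(rec[[3L]])
  n <- as.numeric(rec[[4L]])
  sig <- strsplit(trimws(lines[[2L]]), "\\s+")[[1L]]
  dat <- file.path(dirname(hea), sig[[1L]])
  fmt <- as.integer(sig[[2L]])
  if (is.na(fmt) || fmt != 16L)
    abort_format(sprintf("%s: only format 16 supported (got %s)", hea,
                         sig[[2L]]))
  gainspec <- if (length(sig) >= 3L) sig[[3L]] else as.character(WFDB_DEFAULT_GAIN)
  gainspec <- sub("/.*$", "", gainspec)           # strip units
  baseline <- 0
  if (grepl("\\(", gainspec)) {
    baseline <- as.numeric(sub("^.*\\(([^)]*)\\).*$", "\\1", gainspec))
    gainspec <- sub("\\(.*$", "", gainspec)
  }
  gain <- as.numeric(gainspec)
  if (is.na(gain) || gain == 0) gain <- WFDB_DEFAULT_GAIN
  if (!file.exists(dat)) abort_io(sprintf("file not found: %s", dat))
  adu <- readBin(dat, "integer", n = n, size = 2L, signed = TRUE,
                 endian = "little")
  if (length(adu) < n)
    abort_format(sprintf("%s: expected %d samples, file holds %d",
                         dat, n, length(adu)))
  ecg_record(record_id, fs, (adu - baseline) / gain)
}

write_wfdb_record <- function(record, path, gain = WFDB_DEFAULT_GAIN) {
  base <- sub("\\.hea$", "", path)
  id <- record$record_id
  adu <- as.integer(round(record$samples * gain))
  if (any(abs(adu) > 32767L))
    abort_param("amplitude exceeds the int16 range of format 16 at this gain")
  checksum <- sum(adu) %% 65536L
  if (checksum > 32767L) checksum <- checksum - 65536L
  hea <- c(sprintf("%s 1 %g %d", id, record$sampling_rate_hz,
                   record$n_samples),
           sprintf("%s.dat 16 %g/mV 16 0 %d %d 0 ECG", basename(base), gain,
                   if (length(adu)) adu[[1L]] else 0L, checksum))
  writeLines(hea, paste0(base, ".hea"))
  writeBin(adu, paste0(base, ".dat"), size = 2L, endian = "little")
  invisible(base)
}

## --- MIT annotation stream ------------------------------------------------

ann_put_word <- function(word) {
  w <- as.integer(word)
  if (w > 32767L) w <- w - 65536L
  w
}

write_wfdb_annotations <- function(samples, labels, path) {
  samples <- as.numeric(samples)
  if (length(samples) > 1L && any(diff(samples) < 0))
    abort_format("annotation samples must be non-decreasing")
  if (!all(labels %in% names(ANN_CODE)))
    abort_format("annotation labels must be 'A' or 'N'")
  words <- integer(0)
  prev <- 0
  for (i in seq_along(samples)) {
    delta <- samples[[i]] - prev
    prev <- samples[[i]]
    if (delta > 1023) {
      words <- c(words,
                 ann_put_word(bitwShiftL(ANN_SKIP, 10L)),
                 ann_put_word(bitwShiftR(as.integer(delta), 16L)),
                 ann_put_word(bitwAnd(as.integer(delta), 0xFFFFL)))
      delta <- 0
    }
    code <- ANN_CODE[[labels[[i]]]]
    words <- c(words, ann_put_word(bitwOr(bitwShiftL(code, 10L),
                                          as.integer(delta))))
  }
  words <- c(words, 0L)  # EOF word
  writeBin(words, path, size = 2L, endian = "little")
  invisible(path)
}

read_wfdb_annotations <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("file not found: %s", path))
  raw_words <- readBin(path, "integer", n = file.size(path) %/% 2L,
                       size = 2L, signed = FALSE, endian = "little")
  samples <- numeric(0)
  labels <- character(0)
  t <- 0
  i <- 1L
  while (i <= length(raw_words)) {
    w <- raw_words[[i]]
    code <- bitwShiftR(w, 10L)
    interval <- bitwAnd(w, 0x3FFL)
    if (w == 0L) break                       # EOF
    if (code == ANN_SKIP && interval == 0L) {
      if (i + 2L > length(raw_words))
        abort_format(sprintf("%s: truncated SKIP operand", path))
      t <- t + bitwShiftL(raw_words[[i + 1L]], 16L) + raw_words[[i + 2L]]
      i <- i + 3L
      next
    }
    t <- t + interval
    hit <- names(ANN_CODE)[match(code, ANN_CODE)]
    if (!is.na(hit)) {
      samples <- c(samples, t)
      labels <- c(labels, hit)
    }
    i <- i + 1L
  }
  list(sample = samples, label = labels)
}
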