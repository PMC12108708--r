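test_that("csv record round-trip preserves amplitudes to 1e-9", {
  r <- ecg_record("x01", 100, c(0.1, 0.2, 0.3))
  f <- withr::local_tempfile(fileext = ".csv")
  write_record(r, f, "csv")
  back <- read_record(f, "csv")
  expect_equal(back$record_id, "x01")
  expect_equal(back$sampling_rate_hz, 100)
  expect_equal(back$samples, c(0.1, 0.2, 0.3), tolerance = 1e-12)

  set.seed(7)
  r2 <- ecg_record("rt", 100, rnorm(1000))
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_record(r2, f2, "csv")
  expect_lt(max(abs(read_record(f2)$samples - r2$samples)), 1e-9)
})

test_that("csv record reader rejects malformed input with line context", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines("x01,100", f)   # header only
  expect_error(read_record(f), class = "osadetect_format_error")

  writeLines(c("x01,100", "0.1", "oops"), f)
  expect_error(read_record(f), "line 3", class = "osadetect_format_error")

  writeLines(c("x01,-5", "0.1"), f)
  expect_error(read_record(f), class = "osadetect_format_error")

  expect_error(read_record(file.path(tempdir(), "nope.csv")),
               class = "osadetect_io_error")
})

test_that("qrs text reader collapses duplicates and rejects disorder", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("100", "250", "400"), f)
  expect_equal(read_qrs_track(f)$sample_indices, c(100, 250, 400))

  writeLines(c("100", "100", "250"), f)
  expect_warning(tr <- read_qrs_track(f), "duplicate")
  expect_equal(tr$sample_indices, c(100, 250))
  expect_equal(attr(tr, "n_duplicates"), 1L)

  writeLines(c("250", "100"), f)
  expect_error(suppressWarnings(read_qrs_track(f)),
               class = "osadetect_format_error")
  writeLines(c("-5", "100"), f)
  expect_error(suppressWarnings(read_qrs_track(f)),
               class = "osadetect_format_error")
})

test_that("apnea text dialect maps minutes to start samples", {
  f <- withr::local_tempfile(fileext = ".apn")
  writeLines(c("A", "N"), f)
  tr <- read_apnea_track(f, sampling_rate_hz = 100, window_s = 60)
  expect_equal(tr$labels, c("A", "N"))
  expect_equal(tr$start_samples, c(0, 6000))

  writeLines(character(0), f)
  expect_length(read_apnea_track(f)$labels, 0)

  writeLines("X", f)
  expect_error(read_apnea_track(f), "line 1",
               class = "osadetect_format_error")
})

test_that("all three track types round-trip in the text dialects", {
  dir <- withr::local_tempdir()
  q <- qrs_track("r1", c(0, 120, 7000))
  a <- apnea_track("r1", c("N", "A"), c(0, 6000), 6000)
  qf <- file.path(dir, "r1.qrs.txt")
  af <- file.path(dir, "r1.apn.txt")
  write_qrs_track(q, qf)
  write_apnea_track(a, af)
  expect_equal(read_qrs_track(qf, record_id = "r1")$sample_indices,
               q$sample_indices)
  back <- read_apnea_track(af, record_id = "r1")
  expect_equal(back$labels, a$labels)
  expect_equal(back$start_samples, a$start_samples)

  cf <- file.path(dir, "r1.apn.csv")
  write_apnea_track(a, cf, "csv")
  backc <- read_apnea_track(cf, dialect = "csv", record_id = "r1")
  expect_equal(backc$labels, a$labels)
})

test_that("wfdb record dialect round-trips to its quantization step", {
  set.seed(7)
  r <- ecg_record("w01", 100, rnorm(1000))
  base <- file.path(withr::local_tempdir(), "w01")
  write_record(r, base, "wfdb")
  expect_true(file.exists(paste0(base, ".hea")))
  expect_true(file.exists(paste0(base, ".dat")))
  back <- read_record(paste0(base, ".hea"), "wfdb")
  expect_equal(back$record_id, "w01")
  expect_equal(back$sampling_rate_hz, 100)
  # format 16 at gain 200 quantizes to 1/200 mV
  expect_lt(max(abs(back$samples - r$samples)), 0.5 / 200 + 1e-12)
})

test_that("wfdb annotation dialect round-trips, including long intervals", {
  dir <- withr::local_tempdir()
  # minute-spaced apnea labels need the SKIP extension (interval > 1023)
  a <- apnea_track("r", c("A", "N", "A"), c(0, 6000, 12000), 6000)
  af <- file.path(dir, "r.apn")
  write_apnea_track(a, af, "wfdb_ann")
  back <- read_apnea_track(af, "wfdb_ann", record_id = "r")
  expect_equal(back$labels, a$labels)
  expect_equal(back$start_samples, a$start_samples)

  q <- qrs_track("r", c(3, 80, 200, 100000))
  qf <- file.path(dir, "r.qrs")
  write_qrs_track(q, qf, "wfdb_ann")
  expect_equal(read_qrs_track(qf, "wfdb_ann", record_id = "r")$sample_indices,
               q$sample_indices)
})

test_that("dataset writer produces a complete manifest and reads back", {
  dir <- withr::local_tempdir()
  g1 <- generate_record(synthetic_config(duration_s = 120, seed = 1), "a01")
  g2 <- generate_record(synthetic_config(duration_s = 120, seed = 2), "a02")
  mf <- write_dataset(list(g1$record, g2$record), list(g1$qrs, g2$qrs),
                      list(g1$labels, g2$labels), dir, "csv")
  expect_equal(nrow(mf), 6)  # signal + qrs + labels per record
  expect_setequal(unique(mf$role), c("signal", "qrs", "apnea"))

  back <- read_dataset(dir)
  expect_lt(max(abs(back$records[["a01"]]$samples - g1$record$samples)), 1e-9)
  expect_equal(back$qrs_tracks[["a02"]]$sample_indices,
               g2$qrs$sample_indices)
  expect_equal(back$apnea_tracks[["a01"]]$labels, g1$labels$labels)
})

test_that("dataset writer rejects inconsistent ids and empty input works", {
  dir <- withr::local_tempdir()
  g <- generate_record(synthetic_config(duration_s = 120, seed = 1), "a01")
  bad_q <- qrs_track("zz", c(1, 2))
  expect_error(write_dataset(list(g$record), list(bad_q), list(g$labels),
                             dir, "csv"),
               class = "osadetect_consistency_error")
  mf <- write_dataset(list(), list(), list(), dir, "csv")
  expect_equal(nrow(mf), 0)
})

test_that("out-of-range annotation indices raise a consistency warning", {
  dir <- withr::local_tempdir()
  r <- ecg_record("a01", 100, rnorm(100))
  q <- qrs_track("a01", c(10, 500))    # beyond the 100-sample signal
  a <- apnea_track("a01", character(), numeric(), 6000)
  write_dataset(list(r), list(q), list(a), dir, "csv")
  expect_warning(read_dataset(dir), "beyond signal extent")
})

test_that("domain type invariants are enforced at construction", {
  expect_error(ecg_record("x", 0, c(1, 2)), class = "osadetect_param_error")
  expect_error(ecg_record("x", 100, c(1, NA)), class = "osadetect_param_error")
  expect_error(qrs_track("x", c(5, 5)), class = "osadetect_format_error")
  expect_error(apnea_track("x", c("A", "B"), c(0, 10), 10),
               class = "osadetect_format_error")
  expect_error(apnea_track("x", c("A", "N"), c(0, 15), 10),
               class = "osadetect_format_error")
})
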