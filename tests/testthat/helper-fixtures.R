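# Shared in-code fixtures. Everything is generated at test time; nothing is
# read from disk except files the tests themselves write to tempdirs.

rms <- function(x) sqrt(mean(x^2))

# Sine-wave record of given frequency at fs Hz for dur seconds.
sine_record <- function(freq_hz, fs = 100, dur = 60, id = "sine") {
  t <- seq_len(fs * dur) / fs
  ecg_record(id, fs, sin(2 * pi * freq_hz * t))
}

# A small labelled segment set that a network can separate: class 1 rows
# carry a dense pulse train, class 0 rows a sparse one, plus noise.
tiny_segments <- function(n_per_class = 20, len = 64, seed = 1,
                          partition = NULL) {
  set.seed(seed)
  make_row <- function(n_pulses) {
    x <- rnorm(len, 0, 0.1)
    at <- round(seq(4, len - 4, length.out = n_pulses))
    x[at] <- x[at] + 2
    x
  }
  m <- rbind(
    t(vapply(seq_len(n_per_class), function(i) make_row(4), numeric(len))),
    t(vapply(seq_len(n_per_class), function(i) make_row(12), numeric(len))))
  segment_set(m,
              provenance = data.frame(
                record_id = rep(c("recA", "recB"), each = n_per_class),
                start_sample = rep((seq_len(n_per_class) - 1) * len, 2)),
              labels = rep(c(0, 1), each = n_per_class),
              normalized = FALSE, partition = partition)
}

# Small network configs that keep unit tests fast.
tiny_dual_cfg <- function() {
  dual_branch_config(branch_kernels = c(3L, 5L), blocks_per_branch = 2L,
                     n_filters = 4L, pool_size = 2L, dense_units = 8L,
                     dropout_rate = 0.2)
}

tiny_cnn_cfg <- function() {
  cnn_config(kernel_size = 3L, n_blocks = 2L, n_filters = 4L,
             pool_size = 2L, dense_units = 8L, dropout_rate = 0.2)
}

tiny_train_cfg <- function(epochs = 8L, seed = 1L) {
  train_config(epochs = epochs, batch_size = 16L, seed = seed)
}
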