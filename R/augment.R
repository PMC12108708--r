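## Training-set augmentation (time stretch, amplitude scale, Gaussian noise,
## cropping) and a from-scratch SMOTE balancer. Augmentation is only ever
## applied to the training partition: calling it on anything else is a hard
## leakage error, mirroring the protocol of splitting before augmenting.

#' Augmentation specification
#'
#' Ranges for the four operators. Magnitudes are drawn uniformly from the
#' ranges by the seeded generator; the noise operator always uses
#' `noise_sd`. The defaults are conservative: stretches within +/-10%
#' emulate heart-rate variation, scales within +/-20% emulate sensor gain
#' differences, noise is in units of normalized amplitude, and crops keep at
#' least 90% of the window.
#'
#' @param stretch_range Time-stretch factor interval (default `c(0.9, 1.1)`).
#' @param scale_range Amplitude scale interval (default `c(0.8, 1.2)`).
#' @param noise_sd Gaussian noise standard deviation (default 0.05).
#' @param crop_fraction_range Kept-fraction interval in (0, 1]
#'   (default `c(0.9, 1.0)`).
#' @param per_segment_ops Augmented copies per original (default 1).
#' @param seed Integer seed driving all draws.
#' @return An object of class `augmentation_spec`.
#' @export
augmentation_spec <- function(stretch_range = c(0.9, 1.1),
                              scale_range = c(0.8, 1.2),
                              noise_sd = 0.05,
                              crop_fraction_range = c(0.9, 1.0),
                              per_segment_ops = 1L,
                              seed = 1L) {
  chk <- function(r, nm) {
    if (length(r) != 2L || r[[1L]] > r[[2L]])
      abort_param(sprintf("%s must be an interval lower <= upper", nm))
  }
  chk(stretch_range, "stretch_range")
  chk(scale_range, "scale_range")
  chk(crop_fraction_range, "crop_fraction_range")
  if (noise_sd < 0) abort_param("noise_sd must be non-negative")
  if (any(crop_fraction_range <= 0) || any(crop_fraction_range > 1))
    abort_param("crop fractions must lie in (0, 1]")
  structure(list(stretch_range = stretch_range, scale_range = scale_range,
                 noise_sd = noise_sd,
                 crop_fraction_range = crop_fraction_range,
                 per_segment_ops = as.integer(per_segment_ops),
                 seed = as.integer(seed)),
            class = "augmentation_spec")
}

#' Apply one augmentation operator to a segment
#'
#' All operators preserve length. `stretch` resamples by linear
#' interpolation by factor `magnitude`, then center-crops (factor > 1) or
#' edge-pads with the edge value (factor < 1) back to the original length.
#' `scale` multiplies pointwise. `noise` adds independent Gaussian draws of
#' sd `magnitude`. `crop` keeps a random contiguous fraction `magnitude` of
#' the segment and edge-pads it back. Random draws (`noise`, `crop`) come
#' from R's global generator; seed it for reproducibility.
#'
#' @param segment Numeric vector of length >= 10.
#' @param op One of `"stretch"`, `"scale"`, `"noise"`, `"crop"`.
#' @param magnitude Operator magnitude; stretch/scale must be positive, crop
#'   must lie in (0, 1], noise must be non-negative.
#' @return Numeric vector of the same length as `segment`.
#' @export
augment_segment <- function(segment, op = c("stretch", "scale", "noise",
                                            "crop"), magnitude) {
  op <- match.arg(op)
  x <- as.numeric(segment)
  n <- length(x)
  if (n < 10L) abort_param("segment must have at least 10 samples")
  switch(op,
    scale = {
      if (magnitude <= 0) abort_param("scale magnitude must be positive")
      x * magnitude
    },
    noise = {
      if (magnitude < 0) abort_param("noise magnitude must be non-negative")
      if (magnitude == 0) x else x + stats::rnorm(n, 0, magnitude)
    },
    stretch = {
      if (magnitude <= 0) abort_param("stretch magnitude must be positive")
      m <- as.integer(round(n * magnitude))
      if (m == n) return(x)
      y <- stats::approx(seq_len(n), x, xout = seq(1, n, length.out = m))$y
      fit_to_length(y, n)
    },
    crop = {
      if (magnitude <= 0 || magnitude > 1)
        abort_param("crop fraction must lie in (0, 1]")
      m <- max(1L, as.integer(round(n * magnitude)))
      if (m == n) return(x)
      start <- sample.int(n - m + 1L, 1L)
      fit_to_length(x[start:(start + m - 1L)], n)
    })
}

## Center-crop (too long) or symmetric edge-pad with edge values (too short).
fit_to_length <- function(y, n) {
  m <- length(y)
  if (m == n) return(y)
  if (m > n) {
    off <- (m - n) %/% 2L
    return(y[(off + 1L):(off + n)])
  }
  pad <- n - m
  left <- pad %/% 2L
  c(rep(y[[1L]], left), y, rep(y[[m]], pad - left))
}

#' Augment a training segment set
#'
#' Appends `per_segment_ops` augmented copies per original segment, each
#' labelled as its source, with the operator and magnitude drawn from the
#' spec's ranges by the seeded generator. Refuses (hard leakage error) any
#' set whose partition tag is not `"training"`: augmentation of validation
#' or test data would contaminate the evaluation.
#'
#' @param train A labelled [segment_set()] with `partition = "training"`.
#' @param spec An [augmentation_spec()].
#' @return A [segment_set()] holding the originals followed by the augmented
#'   copies; provenance of copies records the source row and operator. The
#'   draw log (operator, magnitude per copy) is in attribute `audit`.
#' @export
augment_training_set <- function(train, spec = augmentation_spec()) {
  stopifnot(inherits(train, "segment_set"), inherits(spec, "augmentation_spec"))
  if (is.null(train$partition) || train$partition != "training")
    abort_leakage("augmentation is restricted to the training partition")
  if (is.null(train$labels)) abort_param("training set must be labelled")
  set.seed(spec$seed)
  n <- nrow(train$segments)
  ops <- c("stretch", "scale", "noise", "crop")
  total <- n * spec$per_segment_ops
  aug <- matrix(0, total, train$segment_len)
  audit <- data.frame(source_row = integer(total), op = character(total),
                      magnitude = numeric(total), stringsAsFactors = FALSE)
  row <- 0L
  for (i in seq_len(n)) {
    seg <- train$segments[i, ]
    for (j in seq_len(spec$per_segment_ops)) {
      op <- ops[[sample.int(4L, 1L)]]
      mag <- switch(op,
        stretch = stats::runif(1, spec$stretch_range[[1L]],
                               spec$stretch_range[[2L]]),
        scale = stats::runif(1, spec$scale_range[[1L]],
                             spec$scale_range[[2L]]),
        noise = spec$noise_sd,
        crop = stats::runif(1, spec$crop_fraction_range[[1L]],
                            spec$crop_fraction_range[[2L]]))
      seg <- augment_segment(seg, op, mag)   # ops compose in draw order
      row <- row + 1L
      aug[row, ] <- seg
      audit[row, ] <- list(i, op, mag)
    }
  }
  prov_aug <- data.frame(
    record_id = paste0(train$provenance$record_id[audit$source_row],
                       "+aug"),
    start_sample = train$provenance$start_sample[audit$source_row],
    stringsAsFactors = FALSE)
  out <- segment_set(rbind(train$segments, aug),
                     provenance = rbind(train$provenance, prov_aug),
                     labels = c(train$labels,
                                train$labels[audit$source_row]),
                     normalized = train$normalized,
                     partition = "training")
  attr(out, "audit") <- audit
  out
}

#' SMOTE parameters
#'
#' @param k_neighbors Number of nearest minority neighbors considered
#'   (default 5); must be below the minority class size.
#' @param seed Integer seed.
#' @return An object of class `smote_params`.
#' @export
smote_params <- function(k_neighbors = 5L, seed = 1L) {
  k_neighbors <- as.integer(k_neighbors)
  if (is.na(k_neighbors) || k_neighbors < 1L)
    abort_param("k_neighbors must be a positive integer")
  structure(list(k_neighbors = k_neighbors, seed = as.integer(seed),
                 target = "equalize"),
            class = "smote_params")
}

#' Balance classes with SMOTE
#'
#' Canonical synthetic minority over-sampling: each synthetic point is
#' `x + lambda * (neighbor - x)` for a uniformly drawn minority base `x`,
#' one of its `k` nearest minority neighbors (Euclidean), and
#' `lambda ~ U(0, 1)`. The minority class is oversampled up to the majority
#' count; originals are preserved verbatim and come first in the output.
#'
#' @param features Numeric matrix, one sample per row.
#' @param labels Binary 0/1 vector, both classes present.
#' @param params An [smote_params()].
#' @return List with `features` (originals then synthetics) and `labels`;
#'   class counts in the result are exactly equal.
#' @export
smote_balance <- function(features, labels, params = smote_params()) {
  features <- as.matrix(features)
  labels <- as.numeric(labels)
  if (nrow(features) != length(labels))
    abort_param("features and labels must align")
  tab <- table(factor(labels, levels = c(0, 1)))
  if (any(tab == 0)) abort_param("both classes must be present")
  if (tab[["0"]] == tab[["1"]])
    return(list(features = features, labels = labels))
  minority <- if (tab[["0"]] < tab[["1"]]) 0 else 1
  min_idx <- which(labels == minority)
  n_min <- length(min_idx)
  if (n_min <= params$k_neighbors)
    abort_param(sprintf(
      "minority class size (%d) must exceed k_neighbors (%d)",
      n_min, params$k_neighbors))
  n_syn <- as.integer(abs(tab[["1"]] - tab[["0"]]))
  xm <- features[min_idx, , drop = FALSE]
  ## k nearest minority neighbors of each minority point (self excluded)
  d <- as.matrix(stats::dist(xm))
  diag(d) <- Inf
  nn <- matrix(apply(d, 1L, function(r) order(r)[seq_len(params$k_neighbors)]),
               nrow = n_min, ncol = params$k_neighbors, byrow = TRUE)
  set.seed(params$seed)
  base <- sample.int(n_min, n_syn, replace = TRUE)
  pick <- sample.int(params$k_neighbors, n_syn, replace = TRUE)
  lambda <- stats::runif(n_syn)
  syn <- xm[base, , drop = FALSE] +
    lambda * (xm[nn[cbind(base, pick)], , drop = FALSE] -
                xm[base, , drop = FALSE])
  list(features = rbind(features, syn),
       labels = c(labels, rep(minority, n_syn)))
}
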