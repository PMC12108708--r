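test_that("augmentation operators preserve length and basic identities", {
  v <- c(1, -1, 0.5, rep(0.2, 12))
  expect_equal(augment_segment(v, "scale", 2), v * 2)
  expect_equal(sd(augment_segment(v, "scale", 2)), 2 * sd(v))
  expect_equal(augment_segment(v, "noise", 0), v)
  expect_lt(max(abs(augment_segment(v, "stretch", 1) - v)), 1e-9)
  set.seed(1)
  for (op in c("stretch", "scale", "noise", "crop")) {
    mag <- switch(op, stretch = 1.07, scale = 0.9, noise = 0.05, crop = 0.93)
    expect_length(augment_segment(rnorm(200), op, mag), 200)
  }
})

test_that("illegal operator magnitudes are rejected", {
  v <- rnorm(50)
  expect_error(augment_segment(v, "stretch", 0), class = "osadetect_param_error")
  expect_error(augment_segment(v, "crop", 1.2), class = "osadetect_param_error")
  expect_error(augment_segment(v, "crop", 0), class = "osadetect_param_error")
  expect_error(augment_segment(v, "noise", -1), class = "osadetect_param_error")
  expect_error(augment_segment(rnorm(5), "scale", 1),
               class = "osadetect_param_error")
})

test_that("training-set augmentation doubles counts and keeps labels", {
  tr <- tiny_segments(50, partition = "training")
  aug <- augment_training_set(tr, augmentation_spec(seed = 5))
  expect_equal(nrow(aug$segments), 200)
  # label multiset doubled per class; proportions unchanged
  expect_equal(sum(aug$labels == 1), 2 * sum(tr$labels == 1))
  expect_equal(mean(aug$labels), mean(tr$labels))
  # each copy labelled as its source
  audit <- attr(aug, "audit")
  expect_equal(aug$labels[101:200], tr$labels[audit$source_row])
  # originals preserved verbatim, first in order
  expect_identical(aug$segments[1:100, ], tr$segments)
})

test_that("augmentation is deterministic under the seed", {
  tr <- tiny_segments(10, partition = "training")
  a1 <- augment_training_set(tr, augmentation_spec(seed = 9))
  a2 <- augment_training_set(tr, augmentation_spec(seed = 9))
  expect_identical(a1$segments, a2$segments)
  a3 <- augment_training_set(tr, augmentation_spec(seed = 10))
  expect_false(identical(a3$segments, a1$segments))
})

test_that("augmenting a non-training partition is a hard leakage error", {
  va <- tiny_segments(10, partition = "validation")
  expect_error(augment_training_set(va), class = "osadetect_leakage_error")
  untagged <- tiny_segments(10)
  expect_error(augment_training_set(untagged),
               class = "osadetect_leakage_error")
})

test_that("SMOTE equalizes counts with originals preserved first", {
  set.seed(2)
  x <- rbind(matrix(rnorm(200), 100, 2),
             matrix(rnorm(40, mean = 4), 20, 2))
  y <- c(rep(0, 100), rep(1, 20))
  out <- smote_balance(x, y, smote_params(seed = 3))
  expect_equal(sum(out$labels == 0), 100)
  expect_equal(sum(out$labels == 1), 100)
  expect_identical(out$features[1:120, ], x)
  expect_equal(out$labels[1:120], y)

  # already balanced input returned unchanged
  xb <- x[81:120, ]
  yb <- y[81:120]
  same <- smote_balance(xb, yb)
  expect_identical(same$features, xb)
})

test_that("SMOTE synthetics lie on the segment between base and neighbor", {
  # 1-D minority at {0, 1} with k = 1: all synthetics must lie in [0, 1]
  x <- matrix(c(rnorm(50, 10), 0, 1), ncol = 1)
  y <- c(rep(0, 50), 1, 1)
  for (seed in 1:20) {
    out <- smote_balance(x, y, smote_params(k_neighbors = 1, seed = seed))
    syn <- out$features[out$labels == 1, , drop = FALSE][-(1:2), ,
                                                         drop = FALSE]
    expect_true(all(syn >= 0 & syn <= 1))
  }

  # collinearity identity in higher dimension
  set.seed(8)
  xm <- rbind(matrix(rnorm(300), 100, 3),
              matrix(rnorm(45, mean = 5), 15, 3))
  ym <- c(rep(0, 100), rep(1, 15))
  out <- smote_balance(xm, ym, smote_params(k_neighbors = 3, seed = 4))
  syn <- out$features[-(1:115), , drop = FALSE]
  minority <- xm[ym == 1, ]
  pairs <- utils::combn(nrow(minority), 2)
  for (i in seq_len(nrow(syn))) {
    # some minority pair (base, neighbor) brackets the synthetic exactly
    gaps <- apply(pairs, 2, function(p) {
      a <- minority[p[1], ]; b <- minority[p[2], ]
      sqrt(sum((a - syn[i, ])^2)) + sqrt(sum((b - syn[i, ])^2)) -
        sqrt(sum((a - b)^2))
    })
    expect_lt(min(abs(gaps)), 1e-6)
  }
})

test_that("SMOTE rejects degenerate inputs with informative errors", {
  x <- matrix(rnorm(20), 10, 2)
  expect_error(smote_balance(x, rep(1, 10)), class = "osadetect_param_error")
  y <- c(rep(0, 7), rep(1, 3))
  expect_error(smote_balance(x, y, smote_params(k_neighbors = 5)),
               "k_neighbors", class = "osadetect_param_error")
})

test_that("SMOTE is deterministic under the seed", {
  set.seed(2)
  x <- rbind(matrix(rnorm(120), 60, 2), matrix(rnorm(24, 3), 12, 2))
  y <- c(rep(0, 60), rep(1, 12))
  o1 <- smote_balance(x, y, smote_params(seed = 7))
  o2 <- smote_balance(x, y, smote_params(seed = 7))
  expect_identical(o1$features, o2$features)
})
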