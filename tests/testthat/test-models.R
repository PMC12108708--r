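test_that("network builders produce the documented layer shapes", {
  spec <- build_cnn(6000)
  layers <- spec$layers
  out <- layers[nrow(layers), ]
  expect_equal(out$out_len, 1)
  expect_equal(out$activation, "sigmoid")
  expect_true(any(grepl("dropout\\(0.50\\)", layers$layer)))
  # two pool-2 blocks: flattened length 1500 x n_filters
  flat <- layers[layers$layer == "flatten", ]
  expect_equal(flat$out_len, 1500 * 32)

  dual <- build_dual_branch(6000)
  expect_length(dual$branches, 2)
  expect_equal(vapply(dual$branches, `[[`, 0L, "kernel"), c(3L, 5L))
  flats <- dual$layers[dual$layers$layer == "flatten", ]
  concat <- dual$layers[grepl("concatenate", dual$layers$layer), ]
  expect_equal(concat$out_len, sum(flats$out_len))
  expect_equal(dual$l2_coeff, 1e-4)
  expect_equal(dual$dropout_rate, 0.5)
})

test_that("builders reject inputs the pooling pyramid cannot support", {
  expect_error(build_cnn(8), class = "osadetect_param_error")
  expect_error(build_cnn(18, cnn_config(n_blocks = 4)),
               class = "osadetect_param_error")
  expect_error(dual_branch_config(branch_kernels = c(3, 3)),
               class = "osadetect_param_error")
  expect_error(conv_block_spec(4), class = "osadetect_param_error")
  expect_error(cnn_config(dropout_rate = 1), class = "osadetect_param_error")
})

test_that("training is reproducible and learns a separable problem", {
  tr <- tiny_segments(30, seed = 1, partition = "training")
  va <- tiny_segments(10, seed = 2, partition = "validation")
  va$provenance$record_id <- paste0(va$provenance$record_id, "v")
  spec <- build_dual_branch(64, tiny_dual_cfg())
  m1 <- train_model(spec, tr, va, tiny_train_cfg(seed = 3))
  m2 <- train_model(spec, tr, va, tiny_train_cfg(seed = 3))
  expect_equal(tail(m1$history$val_loss, 1), tail(m2$history$val_loss, 1),
               tolerance = 1e-6)
  expect_identical(m1$params$dense_W, m2$params$dense_W)
  expect_gte(max(m1$history$train_acc), 0.95)
  expect_s3_class(m1, "osa_model")
  expect_true(nrow(m1$history) <= 8)
})

test_that("early stopping halts after the patience window", {
  tr <- tiny_segments(30, seed = 1, partition = "training")
  va <- tiny_segments(10, seed = 2, partition = "validation")
  va$provenance$record_id <- paste0(va$provenance$record_id, "v")
  spec <- build_cnn(64, tiny_cnn_cfg())
  tc <- train_config(epochs = 50, batch_size = 16,
                     early_stop_patience = 3, seed = 4)
  m <- train_model(spec, tr, va, tc)
  # stopping rule: at most best-epoch + patience epochs ever run
  best <- which.min(m$history$val_loss)
  expect_lte(nrow(m$history), best + 3)
})

test_that("learning-rate reduction fires after stagnation", {
  tr <- tiny_segments(30, seed = 1, partition = "training")
  va <- tiny_segments(10, seed = 2, partition = "validation")
  va$provenance$record_id <- paste0(va$provenance$record_id, "v")
  spec <- build_cnn(64, tiny_cnn_cfg())
  tc <- train_config(epochs = 30, batch_size = 16, lr_reduce_patience = 2,
                     early_stop_patience = 8, seed = 5)
  m <- train_model(spec, tr, va, tc)
  if (nrow(m$history) > 3) expect_true(min(m$history$lr) <= 0.001)
})

test_that("train/validation provenance overlap is a hard leakage error", {
  tr <- tiny_segments(10, partition = "training")
  va <- tiny_segments(10, partition = "validation")  # same provenance
  spec <- build_cnn(64, tiny_cnn_cfg())
  expect_error(train_model(spec, tr, va, tiny_train_cfg()),
               class = "osadetect_leakage_error")
})

test_that("balanced class weights reduce to unweighted loss when balanced", {
  set.seed(6)
  p <- runif(10)
  y <- rep(c(0, 1), 5)
  w_bal <- rep(10 / (2 * 5), 10)      # balanced weights on balanced data = 1
  lw <- osadetect:::bce_loss_grad(p, y, w_bal)
  lu <- osadetect:::bce_loss_grad(p, y, rep(1, 10))
  expect_lt(abs(lw$loss - lu$loss), 1e-9)
  expect_lt(max(abs(lw$dz - lu$dz)), 1e-9)
})

test_that("threshold selection maximizes Youden's J with ties toward 0.5", {
  # separable scores: any threshold in (0.2, 0.8) is optimal; the candidate
  # nearest 0.5 must be returned
  scores <- c(0.1, 0.2, 0.8, 0.9)
  labels <- c(0, 0, 1, 1)
  th <- osadetect:::youden_threshold(scores, labels)
  expect_equal(th, 0.5)

  # brute-force verification on random score sets
  for (seed in 1:30) {
    set.seed(seed)
    s <- round(runif(40), 2)
    y <- as.numeric(runif(40) < 0.5)
    if (length(unique(y)) < 2) next
    th <- osadetect:::youden_threshold(s, y)
    j_at <- function(t) {
      sum(s >= t & y == 1) / sum(y == 1) +
        sum(s < t & y == 0) / sum(y == 0) - 1
    }
    u <- sort(unique(s))
    cand <- (head(u, -1) + tail(u, -1)) / 2
    expect_lt(max(vapply(cand, j_at, 0)) - j_at(th), 1e-12)
  }
})

test_that("degenerate identical scores fall back to 0.5 with a warning", {
  expect_warning(th <- osadetect:::youden_threshold(rep(0.7, 5),
                                                    c(0, 1, 0, 1, 1)),
                 "identical")
  expect_equal(th, 0.5)
})

test_that("thresholding requires the training partition and predict enforces state", {
  tr <- tiny_segments(20, seed = 1, partition = "training")
  m <- fit_baseline("forest", tr, n_trees = 20, seed = 1)
  expect_error(predict(m, tr), class = "osadetect_state_error")
  va <- tiny_segments(10, seed = 2, partition = "validation")
  expect_error(set_threshold_from_train(m, va),
               class = "osadetect_leakage_error")
  m <- set_threshold_from_train(m, tr)
  pr <- predict(m, tr)
  expect_true(all(pr$score >= 0 & pr$score <= 1))
})

test_that("a score exactly at the threshold is called apnea", {
  m <- structure(list(architecture = "forest", decision_threshold = 0.5),
                 class = c("osa_baseline_model", "osa_model"))
  # bypass model_scores by classifying directly against the threshold
  expect_equal(as.integer(c(0.4, 0.5, 0.6) >= m$decision_threshold),
               c(0L, 1L, 1L))
})

test_that("baselines: CART fits clean data, forest has 100 trees, seeds fix output", {
  set.seed(7)
  x <- rbind(matrix(rnorm(100, 0), 50, 2), matrix(rnorm(100, 6), 50, 2))
  y <- rep(c(0, 1), each = 50)
  tree <- fit_baseline("tree", x, y, seed = 1)
  df <- as.data.frame(x); names(df) <- tree$feature_names
  cls <- as.numeric(as.character(predict(tree$fit, df, type = "class")))
  expect_equal(mean(cls == y), 1.0)

  forest <- fit_baseline("forest", x, y, seed = 1)
  expect_equal(forest$fit$ntree, 100)
  f2 <- fit_baseline("forest", x, y, seed = 1)
  s1 <- osadetect:::model_scores(forest, x)
  s2 <- osadetect:::model_scores(f2, x)
  expect_identical(s1, s2)
  expect_error(fit_baseline("tree", x, rep(1, 100)),
               class = "osadetect_param_error")
})

test_that("inference is deterministic and scores stay in [0, 1]", {
  tr <- tiny_segments(20, seed = 1, partition = "training")
  va <- tiny_segments(8, seed = 2, partition = "validation")
  va$provenance$record_id <- paste0(va$provenance$record_id, "v")
  m <- train_model(build_cnn(64, tiny_cnn_cfg()), tr, va,
                   tiny_train_cfg(epochs = 3))
  m <- set_threshold_from_train(m, tr)
  p1 <- predict(m, va)
  p2 <- predict(m, va)
  expect_identical(p1$score, p2$score)
  expect_true(all(p1$score >= 0 & p1$score <= 1))
  expect_equal(p1$class, as.integer(p1$score >= m$decision_threshold))
})
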