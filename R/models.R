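## Model surface: single-branch and dual-branch 1-D CNN builders, the
## training protocol (Adam, weighted binary cross-entropy, early stopping,
## learning-rate reduction, best-checkpoint restore), train-set-derived
## decision thresholding, and decision-tree / random-forest baselines.
## Fitted models are classed S3 objects ("osa_model") with print, summary,
## predict and plot methods.

#' Convolutional block specification
#'
#' One `conv -> ReLU -> max-pool -> batch-norm` block.
#'
#' @param kernel_size Odd positive kernel width.
#' @param n_filters Number of filters (default 32).
#' @param pool_size Non-overlapping pool width (default 2); must divide the
#'   incoming length.
#' @param use_batch_norm Include batch normalization (default `TRUE`).
#' @return An object of class `conv_block_spec`.
#' @export
conv_block_spec <- function(kernel_size, n_filters = 32L, pool_size = 2L,
                            use_batch_norm = TRUE) {
  kernel_size <- as.integer(kernel_size)
  if (is.na(kernel_size) || kernel_size < 1L || kernel_size %% 2L == 0L)
    abort_param("kernel_size must be a positive odd integer")
  if (pool_size < 1L) abort_param("pool_size must be >= 1")
  structure(list(kernel_size = kernel_size, n_filters = as.integer(n_filters),
                 pool_size = as.integer(pool_size),
                 use_batch_norm = isTRUE(use_batch_norm)),
            class = "conv_block_spec")
}

#' Dual-branch network configuration
#'
#' Two parallel convolution stacks over the same input, with distinct kernel
#' sizes (defaults 3 and 5: one branch sees fine-grained morphology, the
#' other broader context), whose flattened features are concatenated and
#' classified through an L2-regularized dense layer with dropout and a
#' single sigmoid unit.
#'
#' @param branch_kernels Pair of distinct odd kernel sizes (default `c(3, 5)`).
#' @param blocks_per_branch Conv blocks per branch (default 2).
#' @param n_filters Filters per conv layer (default 32).
#' @param pool_size Pool width per block (default 2).
#' @param dense_units Width of the shared dense layer (default 64).
#' @param l2_coeff L2 penalty on dense weights (default 1e-4).
#' @param dropout_rate Dropout rate on the dense layer in `[0, 1)`
#'   (default 0.5).
#' @param use_batch_norm Batch normalization in each block (default `TRUE`).
#' @return An object of class `dual_branch_config`.
#' @export
dual_branch_config <- function(branch_kernels = c(3L, 5L),
                               blocks_per_branch = 2L,
                               n_filters = 32L, pool_size = 2L,
                               dense_units = 64L, l2_coeff = 1e-4,
                               dropout_rate = 0.5, use_batch_norm = TRUE) {
  if (length(branch_kernels) != 2L ||
      branch_kernels[[1L]] == branch_kernels[[2L]])
    abort_param("branch_kernels must be two distinct kernel sizes")
  if (dropout_rate < 0 || dropout_rate >= 1)
    abort_param("dropout_rate must lie in [0, 1)")
  if (l2_coeff < 0) abort_param("l2_coeff must be non-negative")
  structure(list(branch_kernels = as.integer(branch_kernels),
                 blocks_per_branch = as.integer(blocks_per_branch),
                 n_filters = as.integer(n_filters),
                 pool_size = as.integer(pool_size),
                 dense_units = as.integer(dense_units),
                 l2_coeff = l2_coeff, dropout_rate = dropout_rate,
                 use_batch_norm = isTRUE(use_batch_norm)),
            class = "dual_branch_config")
}

#' Single-branch network configuration
#'
#' @param kernel_size Odd kernel size (default 3).
#' @param n_blocks Number of conv blocks (default 2).
#' @inheritParams dual_branch_config
#' @return An object of class `cnn_config`.
#' @export
cnn_config <- function(kernel_size = 3L, n_blocks = 2L, n_filters = 32L,
                       pool_size = 2L, dense_units = 64L,
                       dropout_rate = 0.5, use_batch_norm = TRUE) {
  if (dropout_rate < 0 || dropout_rate >= 1)
    abort_param("dropout_rate must lie in [0, 1)")
  structure(list(kernel_size = as.integer(kernel_size),
                 n_blocks = as.integer(n_blocks),
                 n_filters = as.integer(n_filters),
                 pool_size = as.integer(pool_size),
                 dense_units = as.integer(dense_units),
                 l2_coeff = 0, dropout_rate = dropout_rate,
                 use_batch_norm = isTRUE(use_batch_norm)),
            class = "cnn_config")
}

#' Training configuration
#'
#' @param learning_rate Adam learning rate (default 0.001).
#' @param epochs Maximum epochs (default 50).
#' @param batch_size Mini-batch size (default 32).
#' @param early_stop_patience Epochs without validation-loss improvement
#'   before stopping (default 5).
#' @param lr_reduce_factor Multiplier applied to the learning rate after a
#'   stagnation spell (default 0.5).
#' @param lr_reduce_patience Stagnant epochs before a reduction (default 3).
#' @param class_weighting `"balanced"` (weights inversely proportional to
#'   class frequency) or `"none"`.
#' @param checkpoint_best Restore the best-validation-loss parameters after
#'   training (default `TRUE`).
#' @param seed Integer seed; training is exactly reproducible under it.
#' @return An object of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.001, epochs = 50L,
                         batch_size = 32L, early_stop_patience = 5L,
                         lr_reduce_factor = 0.5, lr_reduce_patience = 3L,
                         class_weighting = c("balanced", "none"),
                         checkpoint_best = TRUE, seed = 1L) {
  class_weighting <- match.arg(class_weighting)
  if (learning_rate <= 0) abort_param("learning_rate must be positive")
  if (lr_reduce_factor <= 0 || lr_reduce_factor >= 1)
    abort_param("lr_reduce_factor must lie in (0, 1)")
  structure(list(learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 early_stop_patience = as.integer(early_stop_patience),
                 lr_reduce_factor = lr_reduce_factor,
                 lr_reduce_patience = as.integer(lr_reduce_patience),
                 class_weighting = class_weighting,
                 checkpoint_best = isTRUE(checkpoint_best),
                 seed = as.integer(seed)),
            class = "train_config")
}

## Validate lengths through the pooling pyramid; returns the final length.
check_pyramid <- function(input_len, pool, blocks, kernel) {
  L <- as.integer(input_len)
  if (L < 16L) abort_param("input_len must be at least 16")
  for (j in seq_len(blocks)) {
    if (L < kernel)
      abort_param("input shorter than the receptive field after pooling")
    if (L %% pool != 0L)
      abort_param(sprintf("pool size %d does not divide length %d at block %d",
                          pool, L, j))
    L <- L %/% pool
  }
  if (L < 1L) abort_param("input fully consumed by pooling")
  L
}

#' Build a single-branch 1-D CNN description
#'
#' Repeated `conv -> ReLU -> max-pool -> batch-norm` blocks, a flatten, a
#' dense ReLU layer with dropout, and a single sigmoid output unit.
#'
#' @param input_len Segment length in samples (>= 16).
#' @param config A [cnn_config()].
#' @return An object of class `osa_net_spec` describing the architecture
#'   (inspect with `print`).
#' @export
build_cnn <- function(input_len, config = cnn_config()) {
  stopifnot(inherits(config, "cnn_config"))
  check_pyramid(input_len, config$pool_size, config$n_blocks,
                config$kernel_size)
  spec <- structure(list(
    architecture = "cnn",
    input_len = as.integer(input_len),
    branches = list(list(kernel = config$kernel_size,
                         blocks = config$n_blocks,
                         n_filters = config$n_filters,
                         pool = config$pool_size,
                         use_batch_norm = config$use_batch_norm)),
    dense_units = config$dense_units,
    dropout_rate = config$dropout_rate,
    l2_coeff = config$l2_coeff,
    config = config), class = "osa_net_spec")
  spec$layers <- describe_layers(spec)
  spec
}

#' Build a dual-branch 1-D CNN description
#'
#' Two parallel convolution stacks with distinct kernel sizes over the same
#' input; their flattened outputs are concatenated and classified through an
#' L2-regularized dense layer with dropout and a single sigmoid unit.
#'
#' @param input_len Segment length in samples (>= 16).
#' @param config A [dual_branch_config()].
#' @return An object of class `osa_net_spec`.
#' @export
build_dual_branch <- function(input_len, config = dual_branch_config()) {
  stopifnot(inherits(config, "dual_branch_config"))
  for (k in config$branch_kernels)
    check_pyramid(input_len, config$pool_size, config$blocks_per_branch, k)
  spec <- structure(list(
    architecture = "dual_branch",
    input_len = as.integer(input_len),
    branches = lapply(config$branch_kernels, function(k)
      list(kernel = k, blocks = config$blocks_per_branch,
           n_filters = config$n_filters, pool = config$pool_size,
           use_batch_norm = config$use_batch_norm)),
    dense_units = config$dense_units,
    dropout_rate = config$dropout_rate,
    l2_coeff = config$l2_coeff,
    config = config), class = "osa_net_spec")
  spec$layers <- describe_layers(spec)
  spec
}

## Human-readable layer table (also used by tests for shape arithmetic).
describe_layers <- function(spec) {
  rows <- list()
  flat_total <- 0L
  for (b in seq_along(spec$branches)) {
    br <- spec$branches[[b]]
    L <- spec$input_len
    c_in <- 1L
    for (j in seq_len(br$blocks)) {
      rows[[length(rows) + 1L]] <- data.frame(
        branch = b, layer = sprintf("conv1d(k=%d)", br$kernel),
        out_len = L, out_channels = br$n_filters, activation = "relu")
      L <- L %/% br$pool
      rows[[length(rows) + 1L]] <- data.frame(
        branch = b, layer = sprintf("max_pool(%d)", br$pool),
        out_len = L, out_channels = br$n_filters, activation = "")
      if (br$use_batch_norm)
        rows[[length(rows) + 1L]] <- data.frame(
          branch = b, layer = "batch_norm", out_len = L,
          out_channels = br$n_filters, activation = "")
      c_in <- br$n_filters
    }
    rows[[length(rows) + 1L]] <- data.frame(
      branch = b, layer = "flatten", out_len = L * c_in, out_channels = 1L,
      activation = "")
    flat_total <- flat_total + L * c_in
  }
  rows[[length(rows) + 1L]] <- data.frame(
    branch = 0L, layer = if (length(spec$branches) > 1L)
      sprintf("concatenate(%d)", flat_total) else "identity",
    out_len = flat_total, out_channels = 1L, activation = "")
  rows[[length(rows) + 1L]] <- data.frame(
    branch = 0L, layer = sprintf("dense(%d)", spec$dense_units),
    out_len = spec$dense_units, out_channels = 1L, activation = "relu")
  rows[[length(rows) + 1L]] <- data.frame(
    branch = 0L, layer = sprintf("dropout(%.2f)", spec$dropout_rate),
    out_len = spec$dense_units, out_channels = 1L, activation = "")
  rows[[length(rows) + 1L]] <- data.frame(
    branch = 0L, layer = "dense(1)", out_len = 1L, out_channels = 1L,
    activation = "sigmoid")
  do.call(rbind, rows)
}

#' @export
print.osa_net_spec <- function(x, ...) {
  cat(sprintf("<osa_net_spec: %s, input_len=%d>\n", x$architecture,
              x$input_len))
  print(x$layers, row.names = FALSE)
  invisible(x)
}

## Leakage guard: any shared (record_id, start_sample) pair between two
## segment sets is an overlap.
provenance_overlap <- function(a, b) {
  ka <- paste(a$provenance$record_id, a$provenance$start_sample)
  kb <- paste(b$provenance$record_id, b$provenance$start_sample)
  length(intersect(ka, kb)) > 0L
}

#' Train a network on labelled segments
#'
#' Optimizes weighted binary cross-entropy with Adam. Validation loss is
#' monitored every epoch: after `lr_reduce_patience` epochs without
#' improvement the learning rate is multiplied by `lr_reduce_factor`, and
#' after `early_stop_patience` such epochs training stops. With
#' `checkpoint_best` the parameters of the best validation epoch are
#' restored. Training is exactly reproducible under `tc$seed`.
#'
#' Train and validation sets must be disjoint by provenance; an overlap is a
#' hard leakage error.
#'
#' @param spec An `osa_net_spec` from [build_cnn()] or [build_dual_branch()].
#' @param train,val Labelled [segment_set()]s with matching segment length.
#' @param tc A [train_config()].
#' @param verbose Print one line per epoch.
#' @return An object of class `osa_model` (architecture `"cnn"` or
#'   `"dual_branch"`) with the training history and an unset decision
#'   threshold (set it with [set_threshold_from_train()]).
#' @export
train_model <- function(spec, train, val, tc = train_config(),
                        verbose = FALSE) {
  stopifnot(inherits(spec, "osa_net_spec"),
            inherits(train, "segment_set"), inherits(val, "segment_set"))
  if (is.null(train$labels) || is.null(val$labels))
    abort_param("train and val must be labelled")
  if (train$segment_len != spec$input_len)
    abort_consistency("segment length does not match spec input_len")
  if (provenance_overlap(train, val))
    abort_leakage("train and validation sets share segments (provenance overlap)")
  set.seed(tc$seed)
  ini <- init_params(spec)
  params <- ini$params
  bn_state <- ini$bn_state
  adam <- adam_init(params)
  Xtr <- train$segments
  ytr <- train$labels
  Xval <- val$segments
  yval <- val$labels
  n <- nrow(Xtr)
  w_class <- if (tc$class_weighting == "balanced")
    c(`0` = n / (2 * sum(ytr == 0)), `1` = n / (2 * sum(ytr == 1)))
  else c(`0` = 1, `1` = 1)
  lr <- tc$learning_rate
  best_val <- Inf
  best_params <- NULL
  best_bn <- NULL
  stagnant <- 0L
  lr_stagnant <- 0L
  hist <- list()
  for (epoch in seq_len(tc$epochs)) {
    ord <- sample.int(n)
    tl <- 0; tacc <- 0; nb <- 0L
    for (start in seq(1L, n, by = tc$batch_size)) {
      rows <- ord[start:min(start + tc$batch_size - 1L, n)]
      Xb <- Xtr[rows, , drop = FALSE]
      yb <- ytr[rows]
      fw <- forward_batch(spec, params, bn_state, Xb, training = TRUE)
      bn_state <- fw$bn_state
      lg <- bce_loss_grad(fw$scores, yb, w_class[as.character(yb)])
      bw <- backward_batch(spec, params, fw, lg$dz)
      if (spec$l2_coeff > 0) {
        bw$grads$dense_W <- bw$grads$dense_W + spec$l2_coeff * params$dense_W
        bw$grads$out_W <- bw$grads$out_W + spec$l2_coeff * params$out_W
      }
      st <- adam_step(params, bw$grads, adam, lr)
      params <- st$params
      adam <- st$state
      tl <- tl + lg$loss
      tacc <- tacc + mean((fw$scores >= 0.5) == (yb == 1))
      nb <- nb + 1L
    }
    vp <- predict_scores_raw(spec, params, bn_state, Xval)
    vl <- bce_loss_grad(vp, yval, rep(1, length(yval)))$loss
    vacc <- mean((vp >= 0.5) == (yval == 1))
    hist[[epoch]] <- data.frame(epoch = epoch, train_loss = tl / nb,
                                train_acc = tacc / nb, val_loss = vl,
                                val_acc = vacc, lr = lr)
    if (verbose)
      message(sprintf("epoch %2d  loss %.4f acc %.3f | val loss %.4f acc %.3f",
                      epoch, tl / nb, tacc / nb, vl, vacc))
    if (vl < best_val - 1e-12) {
      best_val <- vl
      stagnant <- 0L
      lr_stagnant <- 0L
      if (tc$checkpoint_best) {
        best_params <- params
        best_bn <- bn_state
      }
    } else {
      stagnant <- stagnant + 1L
      lr_stagnant <- lr_stagnant + 1L
      if (lr_stagnant >= tc$lr_reduce_patience) {
        lr <- lr * tc$lr_reduce_factor
        lr_stagnant <- 0L
      }
      if (stagnant >= tc$early_stop_patience) break
    }
  }
  if (tc$checkpoint_best && !is.null(best_params)) {
    params <- best_params
    bn_state <- best_bn
  }
  structure(list(architecture = spec$architecture, spec = spec,
                 params = params, bn_state = bn_state,
                 history = do.call(rbind, hist),
                 decision_threshold = NA_real_,
                 train_config = tc),
            class = c("osa_net_model", "osa_model"))
}

predict_scores_raw <- function(spec, params, bn_state, X, chunk = 64L) {
  n <- nrow(X)
  out <- numeric(n)
  for (start in seq(1L, n, by = chunk)) {
    rows <- start:min(start + chunk - 1L, n)
    out[rows] <- forward_batch(spec, params, bn_state,
                               X[rows, , drop = FALSE],
                               training = FALSE, keep_cache = FALSE)$scores
  }
  out
}

## Scores for any osa_model on a plain matrix.
model_scores <- function(model, X) {
  if (inherits(model, "osa_net_model"))
    return(predict_scores_raw(model$spec, model$params, model$bn_state, X))
  if (model$architecture == "tree") {
    df <- as.data.frame(X)
    names(df) <- model$feature_names
    return(stats::predict(model$fit, df)[, "1"])
  }
  if (model$architecture == "forest") {
    colnames(X) <- model$feature_names
    return(stats::predict(model$fit, X, type = "prob")[, "1"])
  }
  abort_state("unknown model architecture")
}

#' Derive the decision threshold from training-set predictions
#'
#' Scores the training partition and chooses the threshold maximizing
#' Youden's J (sensitivity + specificity - 1) over all candidate thresholds
#' (midpoints of consecutive sorted unique scores); ties are broken toward
#' 0.5. Only the training partition may be used — anything else is a
#' leakage error. If all scores are identical the threshold falls back to
#' 0.5 with a warning.
#'
#' @param model A fitted `osa_model`.
#' @param train The training [segment_set()] (partition tag `"training"`).
#' @return The model with `decision_threshold` set.
#' @export
set_threshold_from_train <- function(model, train) {
  stopifnot(inherits(model, "osa_model"), inherits(train, "segment_set"))
  if (is.null(train$partition) || train$partition != "training")
    abort_leakage("decision threshold must be derived from the training partition")
  if (is.null(train$labels)) abort_param("training set must be labelled")
  scores <- model_scores(model, train$segments)
  model$decision_threshold <- youden_threshold(scores, train$labels)
  model
}

## Candidate thresholds are midpoints of consecutive sorted unique scores;
## ties in J are broken toward 0.5.
youden_threshold <- function(scores, labels) {
  u <- sort(unique(scores))
  if (length(u) < 2L) {
    warning("all scores identical; threshold set to 0.5", call. = FALSE)
    return(0.5)
  }
  cand <- (u[-length(u)] + u[-1L]) / 2
  npos <- sum(labels == 1)
  nneg <- sum(labels == 0)
  j <- vapply(cand, function(th) {
    sens <- sum(scores >= th & labels == 1) / npos
    spec <- sum(scores < th & labels == 0) / nneg
    sens + spec - 1
  }, 0)
  best <- which(j >= max(j) - 1e-12)
  cand[best][which.min(abs(cand[best] - 0.5))]
}

#' Predict apnea scores and classes for segments
#'
#' @param object A fitted `osa_model` whose decision threshold has been set.
#' @param segs A [segment_set()] (or numeric matrix) of segments.
#' @param ... Unused.
#' @return Data frame with columns `score` (in `[0, 1]`) and `class`
#'   (0/1; `score >= threshold` is called apnea, so a score exactly at the
#'   threshold is class 1).
#' @export
predict.osa_model <- function(object, segs, ...) {
  if (is.na(object$decision_threshold))
    abort_state("decision threshold unset; call set_threshold_from_train() first")
  X <- if (inherits(segs, "segment_set")) segs$segments else as.matrix(segs)
  s <- model_scores(object, X)
  data.frame(score = s,
             class = as.integer(s >= object$decision_threshold))
}

#' Fit a decision-tree or random-forest baseline
#'
#' The tree is a single CART classifier; the forest is a bootstrap ensemble
#' (default 100 trees) with vote-fraction scores. Both are deterministic
#' under `seed`.
#'
#' @param kind `"tree"` or `"forest"`.
#' @param features Numeric matrix (or [segment_set()]), one sample per row.
#' @param labels Binary 0/1 vector (taken from the segment set if omitted).
#' @param n_trees Trees in the forest (default 100).
#' @param seed Integer seed.
#' @return An `osa_model` (threshold unset).
#' @export
fit_baseline <- function(kind = c("tree", "forest"), features, labels = NULL,
                         n_trees = 100L, seed = 1L) {
  kind <- match.arg(kind)
  if (inherits(features, "segment_set")) {
    labels <- labels %||% features$labels
    features <- features$segments
  }
  features <- as.matrix(features)
  labels <- as.numeric(labels)
  if (length(unique(labels)) < 2L)
    abort_param("both classes must be present")
  feature_names <- paste0("s", seq_len(ncol(features)))
  colnames(features) <- feature_names
  set.seed(seed)
  y <- factor(labels, levels = c(0, 1))
  if (kind == "tree") {
    df <- as.data.frame(features)
    df$.y <- y
    fit <- rpart::rpart(.y ~ ., data = df, method = "class")
  } else {
    fit <- randomForest::randomForest(x = features, y = y, ntree = n_trees)
  }
  structure(list(architecture = kind, fit = fit,
                 feature_names = feature_names,
                 history = NULL, decision_threshold = NA_real_,
                 n_trees = if (kind == "forest") as.integer(n_trees) else NA),
            class = c("osa_baseline_model", "osa_model"))
}

#' @export
print.osa_model <- function(x, ...) {
  cat(sprintf("<osa_model: %s%s, threshold %s>\n", x$architecture,
              if (!is.null(x$history))
                sprintf(", %d epochs trained", nrow(x$history)) else "",
              if (is.na(x$decision_threshold)) "unset"
              else sprintf("%.4f", x$decision_threshold)))
  invisible(x)
}

#' @export
summary.osa_model <- function(object, ...) {
  print(object)
  if (inherits(object, "osa_net_model")) {
    cat("architecture:\n")
    print(object$spec$layers, row.names = FALSE)
    if (!is.null(object$history)) {
      last <- object$history[nrow(object$history), ]
      cat(sprintf("final epoch %d: train loss %.4f acc %.3f | val loss %.4f acc %.3f\n",
                  last$epoch, last$train_loss, last$train_acc,
                  last$val_loss, last$val_acc))
    }
  } else if (object$architecture == "forest") {
    cat(sprintf("random forest with %d trees\n", object$n_trees))
  }
  invisible(object)
}

#' Plot training history
#'
#' @param x A fitted network `osa_model`.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.osa_model <- function(x, ...) {
  if (is.null(x$history)) abort_state("model has no training history")
  h <- x$history
  graphics::matplot(h$epoch, cbind(h$train_loss, h$val_loss), type = "l",
                    lty = 1, col = c("steelblue", "firebrick"),
                    xlab = "epoch", ylab = "binary cross-entropy", ...)
  graphics::legend("topright", c("train", "validation"), lty = 1,
                   col = c("steelblue", "firebrick"), bty = "n")
  invisible(x)
}
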