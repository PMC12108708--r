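## Evaluation layer: confusion counts, accuracy/precision/recall/F1, ROC
## curves with trapezoidal AUC (tie groups collapsed into single steps),
## two-class classification reports, and record-level stratified k-fold
## cross-validation summaries.

#' Confusion counts
#'
#' @param tp,fp,tn,fn Non-negative integer counts with "positive" meaning
#'   the designated positive class.
#' @return An object of class `confusion_counts`.
#' @export
confusion_counts <- function(tp, fp, tn, fn) {
  v <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(v < 0) || anyNA(v)) abort_param("counts must be non-negative")
  if (sum(v) == 0) abort_param("total count must be positive")
  structure(as.list(v), class = "confusion_counts")
}

#' Accuracy, precision, recall and F1 from confusion counts
#'
#' Accuracy is `(tp + tn) / total`, precision `tp / (tp + fp)`, recall
#' `tp / (tp + fn)` and F1 the harmonic mean of precision and recall. A 0/0
#' ratio is reported as `NA` with the `undefined` flag naming the metric —
#' never silently zero.
#'
#' @param counts A [confusion_counts()].
#' @return List with `accuracy`, `precision`, `recall`, `f1` and a character
#'   vector `undefined` naming any 0/0 metrics.
#' @examples
#' m <- binary_metrics(confusion_counts(tp = 52, fp = 8, tn = 17236, fn = 29))
#' round(c(m$precision, m$recall, m$f1), 2)  # 0.87 0.64 0.74
#' @export
binary_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  tp <- counts$tp; fp <- counts$fp; tn <- counts$tn; fn <- counts$fn
  undefined <- character(0)
  ratio <- function(num, den, nm) {
    if (den == 0) {
      undefined <<- c(undefined, nm)
      return(NA_real_)
    }
    num / den
  }
  precision <- ratio(tp, tp + fp, "precision")
  recall <- ratio(tp, tp + fn, "recall")
  f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0) {
    undefined <- c(undefined, "f1")
    NA_real_
  } else 2 * precision * recall / (precision + recall)
  list(accuracy = (tp + tn) / (tp + fp + tn + fn),
       precision = precision, recall = recall, f1 = f1,
       undefined = undefined)
}

#' ROC curve and trapezoidal AUC
#'
#' Sweeps all distinct score values as thresholds (equal scores grouped into
#' one step), so the curve runs from (0, 0) to (1, 1) with non-decreasing
#' coordinates, and integrates it by the trapezoidal rule. With tied scores
#' this equals the Mann-Whitney statistic counting ties as one half.
#'
#' @param scores Numeric vector of classifier scores (larger = more apneic).
#' @param labels Binary 0/1 vector; both classes must be present.
#' @return List with `roc_points` (data frame `fpr`, `tpr`) and `auc`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.numeric(labels)
  if (length(scores) != length(labels))
    abort_param("scores and labels must align")
  npos <- sum(labels == 1)
  nneg <- sum(labels == 0)
  if (npos == 0 || nneg == 0)
    abort_param("both classes must be present for a ROC curve")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- labels[ord]
  ## collapse tie groups into single steps
  grp_end <- c(which(diff(s) != 0), length(s))
  tp_cum <- cumsum(y)[grp_end]
  fp_cum <- cumsum(1 - y)[grp_end]
  tpr <- c(0, tp_cum / npos)
  fpr <- c(0, fp_cum / nneg)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(roc_points = data.frame(fpr = fpr, tpr = tpr), auc = auc)
}

#' Two-class classification report
#'
#' Thresholds the scores (`score >= threshold` is the positive class),
#' computes per-class precision/recall/F1 by treating each class in turn as
#' positive, plus accuracy, the confusion counts for the designated
#' positive class, the ROC curve and AUC.
#'
#' @param y_true Binary 0/1 vector.
#' @param scores Numeric scores in `[0, 1]`.
#' @param threshold Decision threshold in (0, 1).
#' @param positive_class Name for class 1 (default `"apnea"`).
#' @param negative_class Name for class 0 (default `"non-apnea"`).
#' @return An object of class `eval_report` with fields `per_class` (data
#'   frame with precision/recall/F1/support per class), `accuracy`,
#'   `confusion`, `roc_points`, `auc`, `positive_class_name`.
#' @export
classification_report <- function(y_true, scores, threshold = 0.5,
                                  positive_class = "apnea",
                                  negative_class = "non-apnea") {
  if (threshold <= 0 || threshold >= 1)
    abort_param("threshold must lie in (0, 1)")
  y_true <- as.numeric(y_true)
  pred <- as.numeric(scores >= threshold)
  conf <- confusion_counts(tp = sum(pred == 1 & y_true == 1),
                           fp = sum(pred == 1 & y_true == 0),
                           tn = sum(pred == 0 & y_true == 0),
                           fn = sum(pred == 0 & y_true == 1))
  pos <- binary_metrics(conf)
  neg <- binary_metrics(confusion_counts(tp = conf$tn, fp = conf$fn,
                                         tn = conf$tp, fn = conf$fp))
  roc <- roc_auc(scores, y_true)
  per_class <- data.frame(
    class = c(negative_class, positive_class),
    precision = c(neg$precision, pos$precision),
    recall = c(neg$recall, pos$recall),
    f1 = c(neg$f1, pos$f1),
    support = c(sum(y_true == 0), sum(y_true == 1)),
    stringsAsFactors = FALSE)
  structure(list(per_class = per_class, accuracy = pos$accuracy,
                 confusion = conf, roc_points = roc$roc_points,
                 auc = roc$auc, positive_class_name = positive_class),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, digits = 2, ...) {
  cat(sprintf("<eval_report: accuracy %.4f, AUC %.4f (positive = %s)>\n",
              x$accuracy, x$auc, x$positive_class_name))
  tab <- x$per_class
  tab$precision <- round_half_up(tab$precision, digits)
  tab$recall <- round_half_up(tab$recall, digits)
  tab$f1 <- round_half_up(tab$f1, digits)
  print(tab, row.names = FALSE)
  cat(sprintf("confusion: tp=%d fp=%d tn=%d fn=%d\n",
              x$confusion$tp, x$confusion$fp, x$confusion$tn,
              x$confusion$fn))
  invisible(x)
}

#' Round half away from zero at a given number of decimals
#'
#' Display rounding used in reports (2 dp) and fold tables (4 dp);
#' `round_half_up(0.645, 2)` is 0.65, unlike banker's rounding.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Record-level stratified k-fold cross-validation
#'
#' Splits the dataset into `k` folds at the record level (all segments of a
#' record stay together, so no within-record leakage), stratifying records
#' by their apnea fraction. Each fold in turn is held out: the recipe is
#' fitted on the remaining folds and evaluated on the held-out fold.
#'
#' @param dataset A labelled [segment_set()] covering at least `k` records.
#' @param recipe Function `(train, seed) -> osa_model` with its decision
#'   threshold set; the recipe sees only the training folds (network recipes
#'   carve their own inner validation split). See [recipe_forest()].
#' @param k Number of folds (default 5).
#' @param seed Integer seed driving fold assignment and per-fold fits.
#' @return An object of class `fold_summary` with per-fold accuracy and AUC
#'   and their means and sample (n-1) standard deviations.
#' @export
kfold_summary <- function(dataset, recipe, k = 5L, seed = 1L) {
  stopifnot(inherits(dataset, "segment_set"))
  if (k < 2L) abort_param("k must be at least 2")
  if (is.null(dataset$labels)) abort_param("dataset must be labelled")
  recs <- unique(dataset$provenance$record_id)
  if (length(recs) < k)
    abort_param(sprintf("need at least %d records for %d folds",
                        k, k))
  ## stratify records by apnea fraction: order by fraction, deal round-robin
  frac <- vapply(recs, function(r)
    mean(dataset$labels[dataset$provenance$record_id == r]), 0)
  set.seed(derive_seed(seed, 1L))
  ord <- order(frac, stats::runif(length(recs)))   # seeded tie-break
  fold_of <- integer(length(recs))
  fold_of[ord] <- rep_len(seq_len(k), length(recs))
  acc <- numeric(k)
  auc <- numeric(k)
  for (f in seq_len(k)) {
    hold <- recs[fold_of == f]
    te_idx <- which(dataset$provenance$record_id %in% hold)
    tr_idx <- setdiff(seq_len(nrow(dataset$segments)), te_idx)
    train <- subset_segments(dataset, tr_idx, partition = "training")
    test <- subset_segments(dataset, te_idx, partition = "test")
    model <- recipe(train, derive_seed(seed, f + 1L))
    pr <- predict(model, test)
    acc[f] <- mean(pr$class == test$labels)
    auc[f] <- roc_auc(pr$score, test$labels)$auc
  }
  structure(list(fold_accuracy = acc, fold_auc = auc,
                 mean_accuracy = mean(acc),
                 sd_accuracy = stats::sd(acc),
                 mean_auc = mean(auc), sd_auc = stats::sd(auc), k = k),
            class = "fold_summary")
}

#' @export
print.fold_summary <- function(x, ...) {
  cat(sprintf("<fold_summary: %d folds>\n", x$k))
  print(data.frame(fold = seq_len(x$k),
                   accuracy = round_half_up(x$fold_accuracy, 4),
                   roc_auc = round_half_up(x$fold_auc, 4)),
        row.names = FALSE)
  cat(sprintf("mean +/- sd: accuracy %.4f +/- %.4f, AUC %.4f +/- %.4f\n",
              x$mean_accuracy, x$sd_accuracy, x$mean_auc, x$sd_auc))
  invisible(x)
}

#' Model recipes for cross-validation
#'
#' Convenience constructors returning `(train, seed) -> osa_model` closures
#' for [kfold_summary()]: a random forest, a single-branch CNN or a
#' dual-branch CNN. The network recipes carve an inner record-level
#' validation split (for early stopping) out of the training folds, and
#' every recipe derives its decision threshold from its training data only.
#'
#' @param n_trees Trees for the forest recipe.
#' @return A recipe function.
#' @export
recipe_forest <- function(n_trees = 100L) {
  function(train, seed) {
    m <- fit_baseline("forest", train, n_trees = n_trees, seed = seed)
    set_threshold_from_train(m, train)
  }
}

## Inner 80/20 record split of a training fold for early stopping.
inner_val_split <- function(train, seed) {
  parts <- split_by_records(train, c(training = 0.8, validation = 0.2,
                                     test = 0),
                            seed = seed)
  if (is.null(parts$validation)) {
    ## degenerate record count: fall back to a segment-level split
    n <- nrow(train$segments)
    set.seed(seed)
    vi <- sample.int(n, max(1L, n %/% 5L))
    parts <- list(training = subset_segments(train, setdiff(seq_len(n), vi),
                                             partition = "training"),
                  validation = subset_segments(train, vi,
                                               partition = "validation"))
  }
  parts
}

#' @rdname recipe_forest
#' @param config Network configuration ([cnn_config()] or
#'   [dual_branch_config()]).
#' @param tc A [train_config()] (its seed is overridden per fold).
#' @export
recipe_cnn <- function(config = cnn_config(), tc = train_config()) {
  function(train, seed) {
    tc$seed <- seed
    parts <- inner_val_split(train, derive_seed(seed, 97L))
    spec <- build_cnn(train$segment_len, config)
    m <- train_model(spec, parts$training, parts$validation, tc)
    set_threshold_from_train(m, parts$training)
  }
}

#' @rdname recipe_forest
#' @export
recipe_dual_branch <- function(config = dual_branch_config(),
                               tc = train_config()) {
  function(train, seed) {
    tc$seed <- seed
    parts <- inner_val_split(train, derive_seed(seed, 97L))
    spec <- build_dual_branch(train$segment_len, config)
    m <- train_model(spec, parts$training, parts$validation, tc)
    set_threshold_from_train(m, parts$training)
  }
}
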