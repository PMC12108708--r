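test_that("binary metrics reproduce the worked example and perfect case", {
  # non-apnea as positive: 52 correct non-apnea, 8 apnea called non-apnea,
  # 29 non-apnea called apnea, 17236 correct apnea
  m <- binary_metrics(confusion_counts(tp = 52, fp = 8, tn = 17236, fn = 29))
  expect_equal(round_half_up(m$precision, 2), 0.87)
  expect_equal(round_half_up(m$recall, 2), 0.64)
  expect_equal(round_half_up(m$f1, 2), 0.74)

  perf <- binary_metrics(confusion_counts(tp = 10, fp = 0, tn = 5, fn = 0))
  expect_equal(perf$accuracy, 1)
  expect_equal(perf$precision, 1)
  expect_equal(perf$recall, 1)
  expect_equal(perf$f1, 1)
})

test_that("0/0 metric ratios are flagged undefined, never silent zeros", {
  m <- binary_metrics(confusion_counts(tp = 0, fp = 0, tn = 10, fn = 0))
  expect_true(is.na(m$precision))
  expect_true("precision" %in% m$undefined)
  expect_error(confusion_counts(0, 0, 0, 0), class = "osadetect_param_error")
})

test_that("metrics match a brute-force oracle on random confusions", {
  for (seed in 1:250) {
    set.seed(seed)
    v <- sample(0:40, 4, replace = TRUE)
    if (sum(v) == 0) next
    m <- binary_metrics(confusion_counts(v[1], v[2], v[3], v[4]))
    expect_identical(m$accuracy, (v[1] + v[3]) / sum(v))
    if (v[1] + v[2] > 0) expect_identical(m$precision, v[1] / (v[1] + v[2]))
    if (v[1] + v[4] > 0) expect_identical(m$recall, v[1] / (v[1] + v[4]))
  }
})

test_that("ROC/AUC: perfect ranking gives 1, constant scores give 1/2", {
  r <- roc_auc(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1))
  expect_equal(r$auc, 1.0)
  r2 <- roc_auc(rep(0.5, 6), c(0, 1, 0, 1, 1, 0))
  expect_equal(r2$auc, 0.5)
  expect_equal(nrow(r2$roc_points), 2)  # single diagonal step
})

test_that("AUC equals the Mann-Whitney statistic with ties counted half", {
  mann_whitney <- function(s, y) {
    pos <- s[y == 1]; neg <- s[y == 0]
    tot <- 0
    for (p in pos) for (q in neg)
      tot <- tot + (p > q) + 0.5 * (p == q)
    tot / (length(pos) * length(neg))
  }
  for (seed in 1:250) {
    set.seed(seed)
    n <- sample(5:20, 1)
    s <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # force ties
    y <- as.numeric(runif(n) < 0.5)
    if (length(unique(y)) < 2) next
    expect_equal(roc_auc(s, y)$auc, mann_whitney(s, y), tolerance = 1e-12)
  }
})

test_that("AUC agrees with an established independent implementation", {
  skip_if_not_installed("pROC")
  for (seed in 1:25) {
    set.seed(seed)
    s <- runif(60)
    y <- as.numeric(runif(60) < 0.4)
    if (length(unique(y)) < 2) next
    ref <- suppressMessages(as.numeric(
      pROC::auc(pROC::roc(y, s, levels = c(0, 1), direction = "<",
                          quiet = TRUE))))
    expect_equal(roc_auc(s, y)$auc, ref, tolerance = 1e-12)
  }
})

test_that("ROC curves run from (0,0) to (1,1) with monotone coordinates", {
  set.seed(11)
  s <- runif(100)
  y <- as.numeric(runif(100) < 0.3)
  pts <- roc_auc(s, y)$roc_points
  expect_equal(pts$fpr[1], 0)
  expect_equal(pts$tpr[1], 0)
  expect_equal(pts$fpr[nrow(pts)], 1)
  expect_equal(pts$tpr[nrow(pts)], 1)
  expect_true(all(diff(pts$fpr) >= 0))
  expect_true(all(diff(pts$tpr) >= 0))
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(12)
  s <- runif(80)
  y <- as.numeric(runif(80) < 0.5)
  base <- roc_auc(s, y)$auc
  expect_equal(roc_auc(stats::qlogis(s * 0.98 + 0.01), y)$auc, base,
               tolerance = 1e-12)
  expect_equal(roc_auc(s^3, y)$auc, base, tolerance = 1e-12)
})

test_that("ROC rejects single-class labels", {
  expect_error(roc_auc(runif(5), rep(1, 5)), class = "osadetect_param_error")
})

test_that("classification report reproduces the worked example counts", {
  # realize tp=52 fp=8 fn=29 tn=17236 for the non-apnea (score < threshold)
  # class by building scores directly
  y <- c(rep(0, 52), rep(1, 8), rep(0, 29), rep(1, 17236))
  s <- c(rep(0.1, 52), rep(0.1, 8), rep(0.9, 29), rep(0.9, 17236))
  rep_ <- classification_report(y, s, 0.5)
  na_row <- rep_$per_class[rep_$per_class$class == "non-apnea", ]
  expect_equal(round_half_up(na_row$precision, 2), 0.87)
  expect_equal(round_half_up(na_row$recall, 2), 0.64)
  expect_equal(round_half_up(na_row$f1, 2), 0.74)

  # confusion marginals equal the label counts
  conf <- rep_$confusion
  expect_equal(conf$tp + conf$fn, sum(y == 1))
  expect_equal(conf$tn + conf$fp, sum(y == 0))
})

test_that("report is perfect when predictions are perfect", {
  y <- rep(c(0, 1), 10)
  s <- ifelse(y == 1, 0.9, 0.1)
  rep_ <- classification_report(y, s, 0.5)
  expect_equal(rep_$accuracy, 1)
  expect_true(all(rep_$per_class$precision == 1))
  expect_true(all(rep_$per_class$f1 == 1))
})

test_that("swapping the positive class swaps rows and preserves accuracy", {
  set.seed(13)
  y <- as.numeric(runif(200) < 0.4)
  s <- pmin(pmax(y * 0.6 + runif(200) * 0.5, 0.01), 0.99)
  a <- classification_report(y, s, 0.5)
  b <- classification_report(1 - y, 1 - s, 0.5)
  expect_equal(a$accuracy, b$accuracy)
  expect_equal(a$per_class$precision[a$per_class$class == "apnea"],
               b$per_class$precision[b$per_class$class == "non-apnea"])
  expect_equal(a$confusion$tp, b$confusion$tn)
  expect_equal(a$confusion$fp, b$confusion$fn)
})

test_that("fold summary means and sds follow the sample conventions", {
  segs <- tiny_segments(30, seed = 21)
  segs$provenance$record_id <- rep(sprintf("r%02d", 1:10), each = 6)
  fs <- kfold_summary(segs, recipe_forest(n_trees = 15), k = 5, seed = 2)
  expect_length(fs$fold_accuracy, 5)
  expect_equal(fs$mean_accuracy, mean(fs$fold_accuracy), tolerance = 1e-12)
  expect_equal(fs$sd_auc, sd(fs$fold_auc), tolerance = 1e-12)
  expect_error(kfold_summary(tiny_segments(10), recipe_forest(), k = 5),
               class = "osadetect_param_error")
})

test_that("display rounding is half away from zero", {
  expect_equal(round_half_up(0.645, 2), 0.65)
  expect_equal(round_half_up(0.87828, 4), 0.8783)
  expect_equal(round_half_up(-0.645, 2), -0.65)
})
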