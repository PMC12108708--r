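## End-to-end pipeline: simulate (or load) records, condition them, attach
## minute labels, split by record, optionally augment/balance the training
## partition, fit a model, derive the decision threshold from the training
## partition, and evaluate on the held-out test partition. One top-level
## seed fans out deterministically to every stochastic stage.

#' Run the full detection pipeline on a dataset directory
#'
#' Reads a dataset (as written by [write_dataset()] / [generate_dataset()]),
#' runs the conditioning chain, labels segments from the apnea tracks,
#' splits train/validation/test by record, fits the requested model, sets
#' the decision threshold from training predictions, and evaluates on the
#' test partition.
#'
#' @param data_dir Directory holding `manifest.json` and the record files.
#' @param model `"dual_branch"`, `"cnn"`, `"tree"` or `"forest"`.
#' @param seed Top-level seed; all stage seeds derive from it.
#' @param epochs Training epochs for the network models.
#' @param augment Augment the training partition ([augmentation_spec()])
#'   before fitting (default `FALSE`).
#' @param smote Balance the training partition with SMOTE (default `FALSE`).
#' @param fractions Record-level split fractions.
#' @param out_file Optional path for the evaluation report JSON.
#' @return List with `model`, `report` (an `eval_report`), `splits` and the
#'   resolved `config`; written as JSON when `out_file` is given.
#' @export
run_pipeline <- function(data_dir, model = c("dual_branch", "cnn", "tree",
                                             "forest"),
                         seed = 1L, epochs = 20L, augment = FALSE,
                         smote = FALSE,
                         fractions = c(training = 0.5, validation = 0.25,
                                       test = 0.25),
                         out_file = NULL) {
  model <- match.arg(model)
  ds <- read_dataset(data_dir)
  sets <- list()
  for (id in names(ds$records)) {
    rec <- bandpass_filter(ds$records[[id]])
    segs <- segment_and_normalize(rec)
    sets[[id]] <- align_targets_to_segments(ds$apnea_tracks[[id]], segs)
  }
  all_segs <- bind_segment_sets(sets)
  parts <- split_by_records(all_segs, fractions, seed = derive_seed(seed, 1L))
  if (is.null(parts$training) || is.null(parts$test))
    abort_param("split produced an empty training or test partition")
  train <- parts$training
  val <- parts$validation %||% parts$test
  if (augment)
    train <- augment_training_set(
      train, augmentation_spec(seed = derive_seed(seed, 2L)))
  if (smote) {
    bal <- smote_balance(train$segments, train$labels,
                         smote_params(seed = derive_seed(seed, 3L)))
    extra <- nrow(bal$features) - nrow(train$segments)
    train <- segment_set(
      bal$features,
      provenance = rbind(train$provenance,
                         data.frame(record_id = rep("smote", extra),
                                    start_sample = seq_len(extra) - 1)),
      labels = bal$labels, normalized = train$normalized,
      partition = "training")
  }
  fitted <- switch(model,
    dual_branch = {
      spec <- build_dual_branch(train$segment_len)
      train_model(spec, train, val,
                  train_config(epochs = epochs,
                               seed = derive_seed(seed, 4L)))
    },
    cnn = {
      spec <- build_cnn(train$segment_len)
      train_model(spec, train, val,
                  train_config(epochs = epochs,
                               seed = derive_seed(seed, 4L)))
    },
    tree = fit_baseline("tree", train, seed = derive_seed(seed, 4L)),
    forest = fit_baseline("forest", train, seed = derive_seed(seed, 4L)))
  fitted <- set_threshold_from_train(fitted, train)
  pr <- predict(fitted, parts$test)
  report <- classification_report(parts$test$labels, pr$score,
                                  fitted$decision_threshold)
  result <- list(model = fitted, report = report, splits = parts,
                 config = list(model = model, seed = seed, epochs = epochs,
                               augment = augment, smote = smote,
                               fractions = as.list(fractions)))
  if (!is.null(out_file)) write_report_json(report, result$config, out_file)
  result
}

## Serialize an eval_report (plus the resolved run config) as JSON.
write_report_json <- function(report, config, path) {
  jsonlite::write_json(
    list(config = config,
         accuracy = report$accuracy,
         auc = report$auc,
         positive_class = report$positive_class_name,
         per_class = report$per_class,
         confusion = list(tp = report$confusion$tp, fp = report$confusion$fp,
                          tn = report$confusion$tn,
                          fn = report$confusion$fn),
         roc_points = report$roc_points),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
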