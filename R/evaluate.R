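# Confusion-matrix metrics and the attention-ablation harness.

#' Confusion counts with AF as the positive class
#'
#' @param predictions,labels Equal-length 0/1 vectors (1 = AF).
#' @return Object of class `confusion_counts` with `tp`, `fp`, `tn`,
#'   `fn`.
#' @export
confusion_counts <- function(predictions, labels) {
  if (length(predictions) != length(labels))
    stop("`predictions` and `labels` must have equal length")
  if (!all(predictions %in% c(0, 1)) || !all(labels %in% c(0, 1)))
    stop("predictions and labels must be binary 0/1")
  structure(list(tp = sum(predictions == 1 & labels == 1),
                 fp = sum(predictions == 1 & labels == 0),
                 tn = sum(predictions == 0 & labels == 0),
                 fn = sum(predictions == 0 & labels == 1)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(truth = c("AF", "non-AF"),
                              predicted = c("AF", "non-AF")))
  print(m)
  invisible(x)
}

#' Accuracy, sensitivity, specificity and F1 from confusion counts
#'
#' All metrics are percentages rounded to two decimals.  A metric whose
#' denominator is zero (e.g. sensitivity with no AF windows present) is
#' reported as `NA`, never as 0.
#'
#' @param counts A [confusion_counts()].
#' @return One-row data frame with columns `accuracy`, `sensitivity`,
#'   `specificity`, `f1`.
#' @export
af_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  total <- counts$tp + counts$fp + counts$tn + counts$fn
  if (total == 0) stop("empty confusion counts")
  pct <- function(num, den) if (den == 0) NA_real_ else round(100 * num / den, 2)
  data.frame(
    accuracy = pct(counts$tp + counts$tn, total),
    sensitivity = pct(counts$tp, counts$tp + counts$fn),
    specificity = pct(counts$tn, counts$tn + counts$fp),
    f1 = pct(2 * counts$tp, 2 * counts$tp + counts$fp + counts$fn))
}

#' Evaluate a fitted model on one or more test sets
#'
#' @param model A fitted `af_cnn`.
#' @param test A window table, or a named list of window tables.
#' @return For a single test set, a list with `counts` and `metrics`;
#'   for a named list, a data frame with one metric row per test set.
#' @export
evaluate_model <- function(model, test) {
  if (is.data.frame(test)) {
    xy <- windows_to_xy(test)
    cc <- confusion_counts(predict(model, xy$x), xy$y)
    return(list(counts = cc, metrics = af_metrics(cc)))
  }
  rows <- lapply(names(test), function(nm) {
    cbind(data.frame(test_set = nm),
          evaluate_model(model, test[[nm]])$metrics)
  })
  do.call(rbind, rows)
}

#' Strip the attention module from a configuration
#'
#' @param config An [model_config()].
#' @return The identical backbone with `attention = "none"`.
#' @export
strip_attention <- function(config) {
  stopifnot(inherits(config, "af_cnn_config"))
  config$attention <- "none"
  config
}

#' Attention-ablation study
#'
#' For every configuration, trains the model and its attention-stripped
#' twin on the same data with the same seeds, evaluates both on every
#' test set, and averages the metrics over seeds.  The paired rows make
#' the attention contribution directly readable.
#'
#' @param configs List of [model_config()]s (each with an attention
#'   module).
#' @param train_windows Window table used for training.
#' @param test_sets Named list of window tables.
#' @param seeds Integer vector of training seeds (one fit per seed per
#'   variant).
#' @param control An [train_control()]; its seed is replaced per run.
#' @return Data frame with one row per (configuration, variant, test
#'   set): columns `model` (the attention configuration both arms
#'   belong to), `attention` (`"attention"` or `"none"`), `test_set`
#'   and the seed-averaged metrics.
#' @export
ablation_suite <- function(configs, train_windows, test_sets,
                           seeds = 1:5, control = train_control()) {
  if (inherits(configs, "af_cnn_config")) configs <- list(configs)
  stopifnot(is.list(test_sets), !is.null(names(test_sets)))
  rows <- list()
  for (ci in seq_along(configs)) {
    cfg <- configs[[ci]]
    if (cfg$attention == "none")
      stop("ablation needs configurations with an attention module")
    twins <- list(attention = cfg, none = strip_attention(cfg))
    for (vn in names(twins)) {
      per_seed <- lapply(seeds, function(s) {
        ctl <- control
        ctl$seed <- as.integer(s)
        fit <- af_cnn(train_windows, config = twins[[vn]], control = ctl)
        evaluate_model(fit, test_sets)
      })
      for (tn in names(test_sets)) {
        ms <- do.call(rbind, lapply(per_seed,
                                    function(df) df[df$test_set == tn,
                                                    -1, drop = FALSE]))
        rows[[length(rows) + 1]] <- cbind(
          data.frame(model = sprintf("%s-%s+%s", cfg$variant,
                                     cfg$activation, cfg$attention),
                     attention = vn, test_set = tn),
          as.data.frame(as.list(colMeans(ms))))
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
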