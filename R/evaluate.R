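#' Subset (classification) accuracy
#'
#' The strictest multi-label success measure: the fraction of evaluated
#' instances whose predicted label set is an *exact match* of the true set.
#' An empty prediction for an unlabeled instance (a non-enzyme correctly given
#' no mechanism) counts as a match. Padding instances are never evaluated.
#'
#' @param pred An `ml_predictions` object covering all real instances of
#'   `truth`.
#' @param truth The `ml_dataset` holding the true label sets.
#' @return Accuracy in `[0, 1]`.
#' @export
subset_accuracy <- function(pred, truth) {
  stopifnot(inherits(pred, "ml_predictions"), inherits(truth, "ml_dataset"))
  real <- which(!truth$padding)
  at <- match(truth$ids[real], pred$ids)
  if (anyNA(at)) {
    stop("predictions missing for instance(s): ",
         paste(utils::head(truth$ids[real][is.na(at)], 5), collapse = ", "))
  }
  mean(mapply(setequal, pred$labels[at], truth$labels[real]))
}

#' Per-label confusion counts
#'
#' One-vs-rest binarisation over the evaluated (real) instances: for each
#' label the numbers of true positives, false positives, true negatives and
#' false negatives. These tallies feed [micro_metric()] and [macro_metric()].
#' True labels outside `label_space` are dropped when `allow_unknown_truth`
#' (the train/test setting where a test protein's mechanism was never seen in
#' training: its predicted labels still count as false positives, but it can
#' contribute no false negative); otherwise they raise an error, as does any
#' predicted label outside the space.
#'
#' @param pred An `ml_predictions` object.
#' @param truth An `ml_dataset`.
#' @param label_space Label universe; defaults to `truth$label_space`.
#' @param allow_unknown_truth Tolerate true labels outside `label_space`?
#' @return An `ml_counts` matrix (labels x `TP`,`FP`,`TN`,`FN`) with an
#'   `n_evaluated` attribute.
#' @export
confusion_counts <- function(pred, truth, label_space = NULL,
                             allow_unknown_truth = FALSE) {
  stopifnot(inherits(pred, "ml_predictions"), inherits(truth, "ml_dataset"))
  if (is.null(label_space)) label_space <- truth$label_space
  real <- which(!truth$padding)
  at <- match(truth$ids[real], pred$ids)
  if (anyNA(at)) stop("predictions do not cover all evaluated instances")
  bad_pred <- setdiff(unique(unlist(pred$labels[at])), label_space)
  if (length(bad_pred)) {
    stop("predicted label outside label_space: ",
         paste(bad_pred, collapse = ", "))
  }
  bad_truth <- setdiff(unique(unlist(truth$labels[real])), label_space)
  if (length(bad_truth) && !allow_unknown_truth) {
    stop("true label outside label_space: ", paste(bad_truth, collapse = ", "))
  }
  n <- length(real)
  counts <- matrix(0L, nrow = length(label_space), ncol = 4,
                   dimnames = list(label_space, c("TP", "FP", "TN", "FN")))
  for (k in seq_len(n)) {
    y <- intersect(truth$labels[[real[k]]], label_space)
    z <- pred$labels[[at[k]]]
    tp <- intersect(y, z)
    counts[tp, "TP"] <- counts[tp, "TP"] + 1L
    fp <- setdiff(z, y)
    counts[fp, "FP"] <- counts[fp, "FP"] + 1L
    fn <- setdiff(y, z)
    counts[fn, "FN"] <- counts[fn, "FN"] + 1L
  }
  counts[, "TN"] <- n - counts[, "TP"] - counts[, "FP"] - counts[, "FN"]
  attr(counts, "n_evaluated") <- n
  class(counts) <- c("ml_counts", class(counts))
  counts
}

.binary_metric <- function(tp, fp, tn, fn, metric) {
  num_den <- switch(metric,
                    precision = c(tp, tp + fp),
                    recall = c(tp, tp + fn),
                    specificity = c(tn, tn + fp),
                    stop("unknown metric: ", metric))
  if (num_den[2] == 0) return(NA_real_)
  unname(num_den[1] / num_den[2])
}

#' Micro-averaged multi-label metric
#'
#' Pools the confusion counts over all labels, then applies the binary
#' formula. Micro averaging weights labels by frequency.
#'
#' @param counts An `ml_counts` matrix from [confusion_counts()].
#' @param metric `"precision"`, `"recall"` or `"specificity"`.
#' @return Rate in `[0, 1]` (or `NA` when the pooled denominator is 0).
#' @export
micro_metric <- function(counts, metric = c("precision", "recall", "specificity")) {
  metric <- match.arg(metric)
  s <- colSums(unclass(counts))
  .binary_metric(s["TP"], s["FP"], s["TN"], s["FN"], metric)
}

#' Macro-averaged multi-label metric
#'
#' Applies the binary formula per label and averages the per-label values,
#' giving rare and frequent mechanisms equal weight. A label with an undefined
#' value (0/0 — never predicted and never true in the evaluated fold) is
#' scored `empty_value` (default 1: a label absent from the fold was handled
#' perfectly) before averaging.
#'
#' @param counts An `ml_counts` matrix.
#' @param metric `"precision"`, `"recall"` or `"specificity"`.
#' @param empty_value Value for 0/0 labels.
#' @return Rate in `[0, 1]`.
#' @export
macro_metric <- function(counts, metric = c("precision", "recall", "specificity"),
                         empty_value = 1) {
  metric <- match.arg(metric)
  m <- unclass(counts)
  vals <- vapply(seq_len(nrow(m)), function(i) {
    .binary_metric(m[i, "TP"], m[i, "FP"], m[i, "TN"], m[i, "FN"], metric)
  }, numeric(1))
  vals[is.na(vals)] <- empty_value
  mean(vals)
}

#' Standard deviation of a binomial success percentage
#'
#' For a predictor that is correct with probability `P` over `N` independent
#' predictions, the percentage of correct predictions has mean `100 * P` and
#' standard deviation `100 * sqrt(P * (1 - P) / N)`. Two methods whose
#' observed accuracies differ by less than about two such standard deviations
#' are not significantly different.
#'
#' @param P Success probability in `[0, 1]`.
#' @param N Number of predictions (>= 1).
#' @return Standard deviation, in percentage points.
#' @export
binomial_sigma <- function(P, N) {
  if (!is.numeric(P) || P < 0 || P > 1) stop("P must lie in [0, 1]")
  if (!is.numeric(N) || N < 1) stop("N must be >= 1")
  100 * sqrt(P * (1 - P) / N)
}

# ---- predictor specs and evaluation drivers ---------------------------------

#' Predictor specification
#'
#' @param algorithm `"brknn"` or `"direct_transfer"`.
#' @param k,distance BRkNN parameters (ignored for direct transfer).
#' @return A list of class `predictor_spec`.
#' @export
predictor_spec <- function(algorithm = c("brknn", "direct_transfer"), k = 1,
                           distance = c("euclidean", "jaccard")) {
  algorithm <- match.arg(algorithm)
  distance <- match.arg(distance)
  structure(list(algorithm = algorithm, k = k, distance = distance),
            class = "predictor_spec")
}

run_predictor <- function(train, test, spec) {
  if (inherits(spec, "brknn")) return(brknn_predict(spec, test))
  switch(spec$algorithm,
         brknn = brknn_predict(brknn(train, k = spec$k, distance = spec$distance),
                               test),
         direct_transfer = direct_transfer(train, test),
         stop("unknown predictor algorithm: ", spec$algorithm))
}

.build_report <- function(pred, truth, label_space, spec, folds = NULL,
                          seed = NULL, allow_unknown_truth = FALSE) {
  counts <- confusion_counts(pred, truth, label_space = label_space,
                             allow_unknown_truth = allow_unknown_truth)
  real <- which(!truth$padding)
  at <- match(truth$ids[real], pred$ids)
  mis <- lapply(seq_along(real), function(k) {
    y <- truth$labels[[real[k]]]
    z <- pred$labels[[at[k]]]
    if (setequal(y, z)) return(NULL)
    data.frame(id = truth$ids[real[k]],
               true_labels = paste(sort(y), collapse = ";"),
               predicted_labels = paste(sort(z), collapse = ";"),
               fp_labels = paste(sort(setdiff(z, y)), collapse = ";"),
               fn_labels = paste(sort(setdiff(y, z)), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  mis <- do.call(rbind, c(mis, list(NULL)))
  if (is.null(mis)) {
    mis <- data.frame(id = character(), true_labels = character(),
                      predicted_labels = character(), fp_labels = character(),
                      fn_labels = character(), stringsAsFactors = FALSE)
  }
  unknown <- setdiff(unique(unlist(truth$labels[real])), label_space)
  structure(list(
    subset_accuracy = subset_accuracy(pred, truth),
    micro = list(precision = micro_metric(counts, "precision"),
                 recall = micro_metric(counts, "recall"),
                 specificity = micro_metric(counts, "specificity")),
    macro = list(precision = macro_metric(counts, "precision"),
                 recall = macro_metric(counts, "recall"),
                 specificity = macro_metric(counts, "specificity")),
    counts = counts,
    fp_total = sum(unclass(counts)[, "FP"]),
    fn_total = if (allow_unknown_truth && length(unknown)) NA_integer_ else
      sum(unclass(counts)[, "FN"]),
    fn_applicable = !(allow_unknown_truth && length(unknown)),
    mispredictions = mis,
    predictions = pred,
    folds = folds,
    seed = seed,
    n_evaluated = length(real),
    predictor = spec), class = "ml_eval_report")
}

#' @export
print.ml_eval_report <- function(x, ...) {
  cat(sprintf("ml_eval_report over %d instances\n", x$n_evaluated))
  cat(sprintf("  subset accuracy : %.4f\n", x$subset_accuracy))
  cat(sprintf("  micro P/R/Sp    : %.4f / %.4f / %.4f\n",
              x$micro$precision, x$micro$recall, x$micro$specificity))
  cat(sprintf("  macro P/R/Sp    : %.4f / %.4f / %.4f\n",
              x$macro$precision, x$macro$recall, x$macro$specificity))
  cat(sprintf("  FP: %d, FN: %s, mispredicted instances: %d\n", x$fp_total,
              if (x$fn_applicable) as.character(x$fn_total) else "n/a",
              nrow(x$mispredictions)))
  invisible(x)
}

#' Leave-one-out evaluation
#'
#' Each real (non-padding) instance is predicted from a model trained on all
#' other instances; padding anchors always remain in the training side.
#' Metrics are aggregated over the real instances only.
#'
#' @param dataset An `ml_dataset` with at least two real instances.
#' @param spec A [predictor_spec()].
#' @return An `ml_eval_report`.
#' @export
leave_one_out <- function(dataset, spec = predictor_spec()) {
  stopifnot(inherits(dataset, "ml_dataset"))
  real <- which(!dataset$padding)
  if (length(real) < 2) stop("leave-one-out needs at least two real instances")
  preds <- lapply(real, function(i) {
    run_predictor(dataset[-i], dataset[i], spec)
  })
  pred <- ml_predictions(
    dataset$ids[real],
    lapply(preds, function(p) p$labels[[1]]),
    lapply(preds, function(p) p$neighbours[[1]]),
    lapply(preds, function(p) p$distances[[1]]),
    label_space = dataset$label_space)
  .build_report(pred, dataset, dataset$label_space, spec)
}

#' k-fold cross-validation
#'
#' Seeded uniform random partition of the real instances into `folds` folds;
#' each fold is predicted from a model trained on all other instances
#' (padding anchors always train). With `folds` equal to the number of real
#' instances this is exactly [leave_one_out()]. The RNG state of the session
#' is left untouched.
#'
#' @param dataset An `ml_dataset`.
#' @param folds Number of folds (>= 2, <= number of real instances).
#' @param seed Integer seed recorded in the report.
#' @param spec A [predictor_spec()].
#' @return An `ml_eval_report` with the fold assignment in `$folds`.
#' @export
k_fold <- function(dataset, folds, seed, spec = predictor_spec()) {
  stopifnot(inherits(dataset, "ml_dataset"), folds >= 2)
  real <- which(!dataset$padding)
  n <- length(real)
  if (folds > n) stop("partition error: more folds than real instances")
  assign_fold <- local_seed(seed, sample(rep_len(seq_len(folds), n)))
  if (!all(seq_len(folds) %in% assign_fold)) {
    stop("partition error: a fold received zero instances")
  }
  all_pred <- vector("list", n)
  for (f in seq_len(folds)) {
    test_idx <- real[assign_fold == f]
    train_idx <- setdiff(seq_along(dataset$ids), test_idx)
    p <- run_predictor(dataset[train_idx], dataset[test_idx], spec)
    for (k in seq_along(test_idx)) {
      all_pred[[match(test_idx[k], real)]] <-
        list(l = p$labels[[k]], n = p$neighbours[[k]], d = p$distances[[k]])
    }
  }
  pred <- ml_predictions(dataset$ids[real],
                         lapply(all_pred, `[[`, "l"),
                         lapply(all_pred, `[[`, "n"),
                         lapply(all_pred, `[[`, "d"),
                         label_space = dataset$label_space)
  fold_df <- data.frame(id = dataset$ids[real], fold = assign_fold,
                        stringsAsFactors = FALSE)
  .build_report(pred, dataset, dataset$label_space, spec, folds = fold_df,
                seed = seed)
}

#' Train/test evaluation
#'
#' Trains on one dataset and evaluates on a separate one. The two attribute
#' spaces are aligned to their union with absent attributes set to 0 (a test
#' set routinely carries signatures unseen in training). Test instances whose
#' true labels do not exist in the training label space are scored as false
#' positives for anything predicted but contribute no false negatives (their
#' labels are unpredictable); the report then flags `fn_applicable = FALSE`
#' and `fn_total = NA` ("n/a").
#'
#' @param train,test `ml_dataset` objects.
#' @param spec A [predictor_spec()].
#' @return An `ml_eval_report` over the training label space.
#' @export
train_test <- function(train, test, spec = predictor_spec()) {
  al <- union_align(train, test)
  test_real <- al$test[which(!al$test$padding)]
  pred <- run_predictor(al$train, test_real, spec)
  .build_report(pred, test_real, train$label_space, spec,
                allow_unknown_truth = TRUE)
}

# evaluate `expr` under a temporary seed, restoring the caller's RNG state
local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Serialise an evaluation report
#'
#' Writes the metrics as JSON and the misprediction listing as CSV
#' (accession, true and predicted mechanism, false-positive and
#' false-negative labels).
#'
#' @param report An `ml_eval_report`.
#' @param json_path,csv_path Output paths (either may be `NULL` to skip).
#' @return Invisibly, the written paths.
#' @export
write_report <- function(report, json_path = NULL, csv_path = NULL) {
  stopifnot(inherits(report, "ml_eval_report"))
  if (!is.null(json_path)) {
    out <- list(subset_accuracy = report$subset_accuracy,
                micro = report$micro, macro = report$macro,
                fp_total = report$fp_total, fn_total = report$fn_total,
                fn_applicable = report$fn_applicable,
                n_evaluated = report$n_evaluated,
                seed = report$seed,
                predictor = unclass(report$predictor))
    jsonlite::write_json(out, json_path, auto_unbox = TRUE, digits = NA,
                         null = "null", na = "null")
  }
  if (!is.null(csv_path)) {
    utils::write.csv(report$mispredictions, csv_path, row.names = FALSE)
  }
  invisible(c(json_path, csv_path))
}
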