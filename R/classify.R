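#' Binary-relevance k-nearest-neighbour model
#'
#' Multi-label nearest-neighbour classifier: for a query, the `k` nearest
#' training instances are gathered — expanded to the whole "closest ring",
#' i.e. every training instance tied with the k-th smallest distance — and a
#' label is predicted when it appears on at least half of the gathered
#' neighbours (inclusive threshold). With the default `k = 1` and a unique
#' nearest neighbour this copies that neighbour's label set; with several
#' training instances at distance 0 it reduces to the union-style vote of the
#' exact-match baseline. The tie expansion makes predictions deterministic
#' under any reordering of the training instances.
#'
#' @param train Training `ml_dataset` (non-empty).
#' @param k Number of neighbours (>= 1, default 1).
#' @param distance `"euclidean"` or `"jaccard"`.
#' @return An object of class `brknn`.
#' @export
brknn <- function(train, k = 1, distance = c("euclidean", "jaccard")) {
  distance <- match.arg(distance)
  stopifnot(inherits(train, "ml_dataset"), k >= 1)
  if (length(train$ids) == 0) stop("training set is empty")
  structure(list(train = train, k = as.integer(k), distance = distance),
            class = "brknn")
}

#' @export
print.brknn <- function(x, ...) {
  cat(sprintf("brknn model: k=%d, %s distance, %d training instances, %d labels\n",
              x$k, x$distance, length(x$train$ids), length(x$train$label_space)))
  invisible(x)
}

#' Predict label sets with a BRkNN model
#'
#' @param model A [brknn()] model.
#' @param test Test `ml_dataset` over the same attribute space as the
#'   training set.
#' @param tie_tol Absolute tolerance when detecting distance ties.
#' @return An `ml_predictions` object: per test instance the predicted label
#'   set plus neighbour provenance (ids and non-decreasing distances).
#' @export
brknn_predict <- function(model, test, tie_tol = 1e-9) {
  stopifnot(inherits(model, "brknn"), inherits(test, "ml_dataset"))
  train <- model$train
  if (!identical(colnames(test$X), colnames(train$X))) {
    stop("test attribute space does not match the training attribute space")
  }
  D <- dist_matrix(test$X, train$X, model$distance,
                   kind = unique(c(train$attr_kind, test$attr_kind)))
  k <- min(model$k, ncol(D))
  res_labels <- vector("list", nrow(D))
  res_nb <- vector("list", nrow(D))
  res_d <- vector("list", nrow(D))
  for (i in seq_len(nrow(D))) {
    d <- D[i, ]
    kth <- sort(d, partial = k)[k]
    nb <- which(d <= kth + tie_tol)
    nb <- nb[order(d[nb], train$ids[nb])]
    votes <- table(unlist(train$labels[nb]))
    predicted <- names(votes)[2 * votes >= length(nb)]
    res_labels[[i]] <- as.character(predicted)
    res_nb[[i]] <- train$ids[nb]
    res_d[[i]] <- unname(d[nb])
  }
  ml_predictions(test$ids, res_labels, res_nb, res_d,
                 label_space = train$label_space)
}

#' @export
predict.brknn <- function(object, newdata, ...) {
  brknn_predict(object, newdata, ...)
}

#' Container for multi-label predictions
#'
#' @param ids Test instance identifiers.
#' @param labels List of predicted label sets.
#' @param neighbours,distances Optional provenance: per instance, the matched
#'   or neighbouring training ids and their distances (non-decreasing).
#' @param label_space Label universe the predictions live in.
#' @return An object of class `ml_predictions`.
#' @export
ml_predictions <- function(ids, labels, neighbours = NULL, distances = NULL,
                           label_space = NULL) {
  n <- length(ids)
  if (is.null(neighbours)) neighbours <- rep(list(character()), n)
  if (is.null(distances)) distances <- rep(list(numeric()), n)
  stopifnot(length(labels) == n, length(neighbours) == n,
            length(distances) == n)
  structure(list(ids = as.character(ids), labels = lapply(labels, as.character),
                 neighbours = neighbours, distances = distances,
                 label_space = label_space),
            class = "ml_predictions")
}

#' @export
print.ml_predictions <- function(x, ...) {
  cat(sprintf("ml_predictions: %d instances, %d with non-empty label sets\n",
              length(x$ids), sum(lengths(x$labels) > 0)))
  invisible(x)
}

#' Turn predictions into a data frame
#' @param x An `ml_predictions` object.
#' @param ... Unused.
#' @return Data frame with semicolon-joined label and provenance columns.
#' @export
as.data.frame.ml_predictions <- function(x, ...) {
  data.frame(
    test_id = x$ids,
    predicted_labels = vapply(x$labels, paste, "", collapse = ";"),
    neighbour_ids = vapply(x$neighbours, paste, "", collapse = ";"),
    neighbour_distances = vapply(x$distances, function(d) {
      paste(format(d, trim = TRUE, digits = 8), collapse = ";")
    }, ""),
    stringsAsFactors = FALSE)
}

#' Direct-transfer baseline: exact signature match
#'
#' A test protein receives the union of the label sets of all training
#' proteins whose *nonzero signature set is exactly equal* to its own; with no
#' exact match the prediction is empty. This is the "assign the mechanism only
#' when another protein has exactly the same signatures" rule: precise when it
#' fires, but leaving every protein without an exact twin unannotated.
#'
#' @param train,test `ml_dataset` objects with binary attributes over the same
#'   attribute space.
#' @return An `ml_predictions` object (matched training ids as provenance,
#'   distances all 0).
#' @export
direct_transfer <- function(train, test) {
  stopifnot(inherits(train, "ml_dataset"), inherits(test, "ml_dataset"))
  if (!identical(colnames(test$X), colnames(train$X))) {
    stop("test attribute space does not match the training attribute space")
  }
  if (any(train$attr_kind != "binary") || any(test$attr_kind != "binary")) {
    stop("direct transfer requires binary signature attributes")
  }
  key <- function(X) {
    apply(X != 0, 1, function(r) paste(which(r), collapse = ","))
  }
  train_key <- key(train$X)
  test_key <- key(test$X)
  labels <- vector("list", length(test$ids))
  matches <- vector("list", length(test$ids))
  for (i in seq_along(test$ids)) {
    hit <- which(train_key == test_key[i])
    labels[[i]] <- as.character(sort(unique(unlist(train$labels[hit]))))
    matches[[i]] <- train$ids[hit]
  }
  ml_predictions(test$ids, labels, matches,
                 lapply(lengths(matches), numeric),
                 label_space = train$label_space)
}

#' Classify protein pairs with a line separator
#'
#' Applies the straight-line rule "same mechanism iff
#' `euclid <= slope * identity`" (the region to the right of / below a line
#' through the origin in the identity-distance plane; boundary points count as
#' same) and tallies the confusion counts against the pair table's truth.
#'
#' @param pairs Pair table from [pair_table()] (columns `identity`, `euclid`,
#'   `same_mechanism`).
#' @param slope Non-negative line slope (distance per unit identity fraction).
#' @return List with `predicted` (logical vector), `TP`, `FP`, `TN`, `FN`,
#'   `accuracy`, `precision`, `recall`.
#' @export
line_classify <- function(pairs, slope) {
  stopifnot(is.data.frame(pairs), slope >= 0,
            all(c("identity", "euclid", "same_mechanism") %in% names(pairs)))
  pred <- pairs$euclid <= slope * pairs$identity
  truth <- pairs$same_mechanism
  tp <- sum(pred & truth); fp <- sum(pred & !truth)
  tn <- sum(!pred & !truth); fn <- sum(!pred & truth)
  list(predicted = pred, TP = tp, FP = fp, TN = tn, FN = fn,
       accuracy = (tp + tn) / (tp + fp + tn + fn),
       precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_)
}

#' Sweep the line separator over angles
#'
#' Varies the angle of an origin line between 0 and 90 degrees (slope =
#' `tan(angle)`, identity as a fraction on the x axis, Euclidean distance on
#' the y axis) and records the confusion statistics of [line_classify()] at
#' each angle. Explicit slopes can be supplied instead of angles.
#'
#' @param pairs Pair table from [pair_table()].
#' @param angles Angles in degrees, each in `[0, 90)`.
#' @param slopes Slopes (used instead of `angles` when given).
#' @return Data frame with columns `angle`, `slope`, `TP`, `FP`, `TN`, `FN`,
#'   `accuracy`, `precision`, `recall`.
#' @export
line_sweep <- function(pairs, angles = seq(0, 89, by = 1), slopes = NULL) {
  if (is.null(slopes)) {
    stopifnot(all(angles >= 0 & angles < 90))
    slopes <- tan(angles * pi / 180)
  } else {
    angles <- atan(slopes) * 180 / pi
  }
  rows <- lapply(seq_along(slopes), function(k) {
    r <- line_classify(pairs, slopes[k])
    data.frame(angle = angles[k], slope = slopes[k], TP = r$TP, FP = r$FP,
               TN = r$TN, FN = r$FN, accuracy = r$accuracy,
               precision = r$precision, recall = r$recall)
  })
  do.call(rbind, rows)
}
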