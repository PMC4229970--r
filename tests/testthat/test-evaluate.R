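make_pred <- function(ids, labels, space = NULL) {
  ml_predictions(ids, labels, label_space = space)
}

test_that("subset accuracy requires exact set matches, empty included", {
  truth <- ml_dataset(c("P1", "P2", "P3"),
                      matrix(0, 3, 1, dimnames = list(NULL, "s1")),
                      list(c("M0001", "M0002"), character(), "M0001"),
                      label_space = c("M0001", "M0002"))
  all_right <- make_pred(truth$ids, truth$labels)
  expect_equal(subset_accuracy(all_right, truth), 1)
  # empty-vs-empty counts as a match; 2 of 3 exact
  pred <- make_pred(truth$ids, list(c("M0002", "M0001"), character(), "M0002"))
  expect_equal(subset_accuracy(pred, truth), 2 / 3)
  expect_error(subset_accuracy(make_pred("P1", list("M0001")), truth),
               "missing")
})

test_that("confusion counts match hand enumeration on random cases", {
  set.seed(31)
  space <- sprintf("M%04d", 1:5)
  for (r in 1:25) {
    n <- sample(4:15, 1)
    truth_labels <- lapply(seq_len(n), function(i) space[runif(5) < 0.3])
    pred_labels <- lapply(seq_len(n), function(i) space[runif(5) < 0.3])
    truth <- ml_dataset(sprintf("P%d", 1:n), matrix(0, n, 1),
                        truth_labels, label_space = space)
    pred <- make_pred(truth$ids, pred_labels)
    got <- confusion_counts(pred, truth)
    want <- brute_counts(pred_labels, truth_labels, space)
    expect_equal(unclass(got)[, ], want[, ], ignore_attr = TRUE)
    # every label's four cells sum to the evaluated instance count
    expect_true(all(rowSums(unclass(got)) == n))
  }
})

test_that("perfect predictions have zero FP and FN everywhere", {
  d <- toy_dataset()
  counts <- confusion_counts(make_pred(d$ids, d$labels), d)
  expect_true(all(unclass(counts)[, c("FP", "FN")] == 0))
})

test_that("predicted labels outside the label space are rejected", {
  d <- toy_dataset()
  expect_error(
    confusion_counts(make_pred(d$ids, list("M9999", character(),
                                           character(), character())), d),
    "M9999")
})

test_that("micro pools counts, macro averages values", {
  counts <- matrix(c(9, 1, 0, 0,
                     1, 9, 0, 0), nrow = 2, byrow = TRUE,
                   dimnames = list(c("A", "B"), c("TP", "FP", "TN", "FN")))
  class(counts) <- c("ml_counts", class(counts))
  expect_equal(micro_metric(counts, "precision"), 10 / 20)
  expect_equal(macro_metric(counts, "precision"), (0.9 + 0.1) / 2)
  counts2 <- counts
  counts2["B", "FP"] <- 0
  expect_equal(micro_metric(counts2, "precision"), 10 / 11)
  expect_equal(macro_metric(counts2, "precision"), (0.9 + 1.0) / 2)
  # single label: micro = macro = binary value
  one <- counts[1, , drop = FALSE]
  class(one) <- c("ml_counts", class(one))
  expect_equal(micro_metric(one, "precision"), macro_metric(one, "precision"))
})

test_that("micro equals the binary metric on summed counts (random property)", {
  set.seed(32)
  for (r in 1:50) {
    counts <- matrix(rpois(20, 5), ncol = 4,
                     dimnames = list(sprintf("L%d", 1:5),
                                     c("TP", "FP", "TN", "FN")))
    class(counts) <- c("ml_counts", class(counts))
    s <- colSums(unclass(counts))
    expect_equal(micro_metric(counts, "precision"), s["TP"] / (s["TP"] + s["FP"]),
                 ignore_attr = TRUE)
    expect_equal(micro_metric(counts, "recall"), s["TP"] / (s["TP"] + s["FN"]),
                 ignore_attr = TRUE)
    expect_equal(micro_metric(counts, "specificity"), s["TN"] / (s["TN"] + s["FP"]),
                 ignore_attr = TRUE)
    for (m in c("precision", "recall", "specificity")) {
      expect_gte(macro_metric(counts, m), 0)
      expect_lte(macro_metric(counts, m), 1)
    }
  }
})

test_that("specificity stays near 1 when false positives are rare over many labels", {
  # 200 labels, 100 instances, a handful of FP: TN dominates every column
  set.seed(33)
  space <- sprintf("M%04d", 1:200)
  truth_labels <- lapply(1:100, function(i) sample(space, 1))
  pred_labels <- truth_labels
  pred_labels[[1]] <- c(pred_labels[[1]], space[200])   # one spurious label
  truth <- ml_dataset(sprintf("P%d", 1:100), matrix(0, 100, 1), truth_labels,
                      label_space = space)
  counts <- confusion_counts(make_pred(truth$ids, pred_labels), truth)
  expect_gte(micro_metric(counts, "specificity"), 0.997)
  expect_gte(macro_metric(counts, "specificity"), 0.997)
})

test_that("binomial sigma reproduces the closed form", {
  expect_equal(round(binomial_sigma(0.963, 250), 2), 1.19)
  expect_equal(binomial_sigma(0, 100), 0)
  expect_equal(binomial_sigma(1, 100), 0)
  expect_equal(binomial_sigma(0.5, 100), 5)
  expect_error(binomial_sigma(1.2, 10), "\\[0, 1\\]")
  expect_error(binomial_sigma(0.5, 0), ">= 1")
})

test_that("leave-one-out recovers duplicate-pair datasets perfectly", {
  # every instance has an identical-attribute partner with identical labels
  X <- matrix(c(1, 0, 1, 0, 0, 1, 0, 1), nrow = 4, byrow = TRUE,
              dimnames = list(sprintf("P%d", 1:4), c("s1", "s2")))
  d <- ml_dataset(rownames(X), X,
                  list("M0001", "M0001", "M0002", "M0002"))
  r <- leave_one_out(d)
  expect_equal(r$subset_accuracy, 1)
  expect_equal(nrow(r$mispredictions), 0)
  # a mechanism with exactly 2 carriers stays predictable in every fold
  expect_equal(r$micro$recall, 1)
})

test_that("leave-one-out is invariant to instance order", {
  set.seed(34)
  d <- random_dataset(12, 5, 3)
  r1 <- leave_one_out(d)
  perm <- sample(12)
  r2 <- leave_one_out(d[perm])
  expect_equal(r1$subset_accuracy, r2$subset_accuracy)
  expect_equal(sort(r1$mispredictions$id), sort(r2$mispredictions$id))
})

test_that("k-fold is seeded, reproducible, and equals LOO at folds = n", {
  set.seed(35)
  d <- random_dataset(10, 5, 3)
  r1 <- k_fold(d, folds = 2, seed = 7)
  r2 <- k_fold(d, folds = 2, seed = 7)
  expect_identical(r1$folds, r2$folds)
  expect_equal(r1$subset_accuracy, r2$subset_accuracy)
  r3 <- k_fold(d, folds = 2, seed = 8)
  expect_false(identical(r1$folds, r3$folds))
  # folds = n reduces to leave-one-out exactly
  loo <- leave_one_out(d)
  kn <- k_fold(d, folds = 10, seed = 99)
  expect_equal(kn$subset_accuracy, loo$subset_accuracy)
  expect_equal(unclass(kn$counts)[, ], unclass(loo$counts)[, ])
  expect_error(k_fold(d, folds = 11, seed = 1), "partition error")
})

test_that("k-fold leaves the session RNG state untouched", {
  set.seed(36)
  d <- random_dataset(8, 4, 2)
  before <- .Random.seed
  invisible(k_fold(d, folds = 2, seed = 1))
  expect_identical(.Random.seed, before)
})

test_that("train/test aligns attribute unions and flags unpredictable labels", {
  train <- toy_dataset()
  # test set with an unseen signature and an unseen true label
  Xte <- matrix(c(1, 1, 1), 1, dimnames = list("N1", c("s1", "s2", "s9")))
  test <- ml_dataset("N1", Xte, list("M0999"), label_space = "M0999")
  r <- train_test(train, test)
  expect_false(r$fn_applicable)          # true label unpredictable -> n/a FN
  expect_true(is.na(r$fn_total))
  expect_true(r$fp_total >= 0)
  # training set with no labels at all never produces a false positive
  neg_train <- ml_dataset(c("A", "B"),
                          matrix(c(1, 0, 0, 1), 2,
                                 dimnames = list(NULL, c("s1", "s2"))),
                          list(character(), character()),
                          label_space = character())
  r2 <- train_test(neg_train, test)
  expect_equal(r2$fp_total, 0)
})

test_that("padding anchors train but are never evaluated", {
  d <- add_empty_instances(toy_dataset(), 2)
  r <- leave_one_out(d)
  expect_equal(r$n_evaluated, 4)
  expect_false(any(grepl("^__EMPTY_", r$predictions$ids)))
})

test_that("evaluation reports serialise to JSON and CSV", {
  d <- toy_dataset()
  r <- leave_one_out(d)
  js <- tempfile(fileext = ".json")
  cs <- tempfile(fileext = ".csv")
  write_report(r, js, cs)
  back <- jsonlite::read_json(js)
  expect_equal(back$subset_accuracy, r$subset_accuracy)
  expect_equal(back$n_evaluated, 4)
  mis <- utils::read.csv(cs)
  expect_equal(nrow(mis), nrow(r$mispredictions))
})
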