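# Brute-force oracles and fixture builders. The oracles deliberately share no
# code with the implementation paths they check: plain loops over dense
# vectors.

toy_dataset <- function() {
  ann <- data.frame(
    protein = c("P1", "P1", "P2", "P3", "P3", "P4"),
    signature = c("s1", "s2", "s2", "s3", "s4", "s1"),
    stringsAsFactors = FALSE)
  lab <- data.frame(protein = c("P1", "P2", "P3"),
                    label = c("M0001", "M0001", "M0002"),
                    stringsAsFactors = FALSE)
  build_dataset(ann, lab)
}

# random multi-label dataset over binary attributes
random_dataset <- function(n, d, n_labels, density = 0.35,
                           label_rate = 0.4, prefix = "Q") {
  X <- matrix(rbinom(n * d, 1, density), nrow = n,
              dimnames = list(sprintf("%s%03d", prefix, seq_len(n)),
                              sprintf("s%02d", seq_len(d))))
  space <- sprintf("M%04d", seq_len(n_labels))
  labels <- lapply(seq_len(n), function(i) {
    space[runif(n_labels) < label_rate]
  })
  ml_dataset(rownames(X), X, labels, label_space = space)
}

brute_euclid <- function(u, v) {
  s <- 0
  for (k in seq_along(u)) s <- s + (u[k] - v[k])^2
  sqrt(s)
}

brute_jaccard <- function(u, v) {
  inter <- 0; un <- 0
  for (k in seq_along(u)) {
    if (u[k] != 0 && v[k] != 0) inter <- inter + 1
    if (u[k] != 0 || v[k] != 0) un <- un + 1
  }
  if (un == 0) 0 else 1 - inter / un
}

# plain-loop reimplementation of the closest-ring voting rule
brute_brknn <- function(train, test, k = 1, distance = "euclidean") {
  Xtr <- as.matrix(train$X)
  Xte <- as.matrix(test$X)
  dfun <- if (distance == "euclidean") brute_euclid else brute_jaccard
  lapply(seq_len(nrow(Xte)), function(i) {
    d <- vapply(seq_len(nrow(Xtr)), function(j) dfun(Xte[i, ], Xtr[j, ]),
                numeric(1))
    kth <- sort(d)[min(k, length(d))]
    nb <- which(d <= kth + 1e-9)
    labs <- unlist(train$labels[nb])
    if (is.null(labs)) return(character())
    tab <- table(labs)
    sort(names(tab)[2 * tab >= length(nb)])
  })
}

# hand-enumerated per-label confusion counts
brute_counts <- function(pred_labels, true_labels, space) {
  out <- matrix(0L, nrow = length(space), ncol = 4,
                dimnames = list(space, c("TP", "FP", "TN", "FN")))
  for (i in seq_along(pred_labels)) {
    for (lam in space) {
      p <- lam %in% pred_labels[[i]]
      t <- lam %in% true_labels[[i]]
      if (p && t) out[lam, "TP"] <- out[lam, "TP"] + 1L
      else if (p) out[lam, "FP"] <- out[lam, "FP"] + 1L
      else if (t) out[lam, "FN"] <- out[lam, "FN"] + 1L
      else out[lam, "TN"] <- out[lam, "TN"] + 1L
    }
  }
  out
}

expect_same_label_sets <- function(a, b) {
  expect_equal(length(a), length(b))
  for (i in seq_along(a)) {
    expect_identical(as.character(sort(a[[i]])), as.character(sort(b[[i]])))
  }
}
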