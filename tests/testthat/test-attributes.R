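test_that("Euclidean distance on binary vectors is sqrt of the Hamming count", {
  expect_equal(euclidean_distance(c(1, 0, 1), c(1, 0, 1)), 0)
  expect_equal(euclidean_distance(c(1, 0, 0), c(0, 0, 0)), 1)
  expect_equal(euclidean_distance(c(1, 1, 1, 1, 0), c(0, 0, 0, 0, 1)), sqrt(5))
  expect_error(euclidean_distance(c(1, 0), c(1, 0, 1)), "dimension")
  set.seed(11)
  for (r in 1:200) {
    u <- rbinom(12, 1, 0.4); v <- rbinom(12, 1, 0.4)
    expect_equal(euclidean_distance(u, v), sqrt(sum(u != v)))
    expect_equal(euclidean_distance(u, v), euclidean_distance(v, u))
  }
})

test_that("Jaccard distance follows the set formula", {
  expect_equal(jaccard_distance(c(1, 1, 0), c(1, 1, 0)), 0)
  expect_equal(jaccard_distance(c(1, 0, 0), c(0, 1, 1)), 1)   # disjoint
  expect_equal(jaccard_distance(c(1, 1, 0), c(0, 1, 1)), 2 / 3)
  expect_equal(jaccard_distance(c(0, 0), c(0, 0)), 0)         # both empty
  expect_error(jaccard_distance(c(0.5, 1), c(1, 0)), "binary")
  set.seed(12)
  for (r in 1:100) {
    u <- rbinom(10, 1, 0.4); v <- rbinom(10, 1, 0.4)
    expect_equal(jaccard_distance(u, v), brute_jaccard(u, v))
  }
})

test_that("matrix distances agree with the vector definitions", {
  set.seed(13)
  A <- Matrix::Matrix(matrix(rbinom(40, 1, 0.4), 8), sparse = TRUE)
  A <- methods::as(methods::as(A, "generalMatrix"), "CsparseMatrix")
  D <- mechknn:::dist_matrix(A, A, "euclidean")
  J <- mechknn:::dist_matrix(A, A, "jaccard")
  for (i in 1:8) for (j in 1:8) {
    expect_equal(D[i, j], brute_euclid(as.vector(A[i, ]), as.vector(A[j, ])))
    expect_equal(J[i, j], brute_jaccard(as.vector(A[i, ]), as.vector(A[j, ])))
  }
})

test_that("global alignment identity matches the frozen reference values", {
  # reference global aligner (BLOSUM62, gap = 10 + 0.5 per residue) gives
  # alignment length 10 with 3 identities for this classic pair
  expect_equal(pairwise_identity("HEAGAWGHEE", "PAWHEAE"), 0.3)
  expect_equal(pairwise_identity("PAWHEAE", "HEAGAWGHEE"), 0.3)  # symmetric
  expect_equal(pairwise_identity("MKTAYIAKQR", "MKTAYIAKQR"), 1.0)
  expect_equal(pairwise_identity("mktayiakqr", "MKTAYIAKQR"), 1.0)  # case
  expect_equal(pairwise_identity("AAAA", "WWWW"), 0.0)
  expect_error(pairwise_identity("", "ACDE"), "empty")
})

test_that("the bundled EBLOSUM62 matrix parses and is symmetric", {
  m <- read_substitution_matrix(
    system.file("extdata", "EBLOSUM62.txt", package = "mechknn"))
  expect_true(all(c("A", "W", "X", "*") %in% rownames(m)))
  expect_equal(m, t(m))
  expect_equal(m["W", "W"], 11)
  expect_equal(m["A", "A"], 4)
})

test_that("min-Euclidean profiles equal a brute-force scan", {
  X <- matrix(0, 3, 3, dimnames = list(c("P1", "P2", "P3"),
                                       c("s1", "s2", "s3")))
  X["P1", "s1"] <- 1
  X["P2", c("s1", "s2")] <- 1
  X["P3", "s3"] <- 1
  train <- ml_dataset(rownames(X), X, list("M0001", "M0001", "M0002"))
  prof <- min_euclidean_profile(c(1, 1, 0), train)
  expect_equal(unname(prof), c(0, sqrt(3)))  # exact carrier; {s1,s2} vs {s3}
  # brute force over random cases: profile value is the carrier minimum
  set.seed(14)
  for (r in 1:20) {
    d <- random_dataset(8, 6, 3)
    q <- rbinom(6, 1, 0.4)
    prof <- min_euclidean_profile(q, d)
    for (m in d$label_space) {
      carriers <- which(vapply(d$labels, function(l) m %in% l, TRUE))
      want <- if (length(carriers) == 0) NO_CARRIER_DISTANCE else
        min(vapply(carriers, function(i) brute_euclid(q, as.vector(d$X[i, ])),
                   numeric(1)))
      expect_equal(prof[[m]], want)
      # never below the distance to any individual carrier's minimum
      for (i in carriers) {
        expect_lte(prof[[m]], brute_euclid(q, as.vector(d$X[i, ])))
      }
    }
  }
})

test_that("max-identity profiles equal a brute-force scan and use sentinels", {
  store <- c(P1 = "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ",
             P2 = "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVA",
             P3 = "GHIKLMNPQRSTVWYACDEFGHIKLMNPQRST")
  X <- matrix(1, 3, 1, dimnames = list(names(store), "s1"))
  train <- ml_dataset(names(store), X, list("M0001", "M0001", "M0002"),
                      label_space = c("M0001", "M0002", "M0003"))
  prof <- max_identity_profile(store[["P1"]], train, store)
  brute <- vapply(c("M0001", "M0002"), function(m) {
    carriers <- train$ids[vapply(train$labels, function(l) m %in% l, TRUE)]
    max(vapply(carriers, function(a) pairwise_identity(store[["P1"]], store[[a]]),
               numeric(1)))
  }, numeric(1))
  expect_equal(prof[["M0001"]], brute[["M0001"]])
  expect_equal(prof[["M0001"]], 1.0)            # identical carrier present
  expect_equal(prof[["M0002"]], brute[["M0002"]])
  expect_equal(prof[["M0003"]], 0)              # no carriers -> sentinel 0
  expect_error(max_identity_profile("ACDEF", train, store[-1]), "P1")
})

test_that("profile datasets are leave-one-out and carry numeric attributes", {
  d <- toy_dataset()
  p <- profile_dataset(d, "min_euclid")
  expect_equal(colnames(p$X), c("dmin_M0001", "dmin_M0002"))
  expect_true(all(p$attr_kind == "numeric"))
  # P1 {s1,s2}: nearest other M0001 carrier is P2 {s2} at distance 1;
  # nearest M0002 carrier is P3 {s3,s4} at distance 2
  expect_equal(as.vector(p$X["P1", ]), c(1, 2))
  # P3 is the only M0002 carrier: leave-one-out leaves none -> sentinel
  expect_equal(p$X["P3", "dmin_M0002"], NO_CARRIER_DISTANCE)
})

test_that("combining attribute sets concatenates columns and checks labels", {
  d <- toy_dataset()
  dup <- d
  comb <- combine_attribute_sets(list(d, dup), namespaces = c("a", "b"))
  expect_equal(ncol(comb$X), 2 * ncol(d$X))  # widths add
  # doubling every column scales Euclidean distances by sqrt(2)
  D1 <- mechknn:::dist_matrix(d$X, d$X, "euclidean")
  D2 <- mechknn:::dist_matrix(comb$X, comb$X, "euclidean")
  expect_equal(D2, sqrt(2) * D1)
  expect_error(combine_attribute_sets(list(d, dup)), "clash")
  bad <- d
  bad$labels[[1]] <- "M0002"
  expect_error(combine_attribute_sets(list(d, bad), namespaces = c("a", "b")),
               "disagreement")
  reord <- d[rev(seq_along(d$ids))]
  expect_error(combine_attribute_sets(list(d, reord), namespaces = c("a", "b")),
               "different instances")
})

test_that("pair tables enumerate C(n,2) unordered pairs with truth flags", {
  sd <- synth_generate(synth_config(seed = 5, n_families = 2,
                                    orthologs_per_family = 2, n_negatives = 1,
                                    length_band = c(60, 80)))
  pt <- pair_table(sd$dataset, sd$store)
  n <- sum(!sd$dataset$padding)
  expect_equal(nrow(pt), choose(n, 2))
  expect_true(all(pt$accession_a < pt$accession_b))
  same <- pt$same_mechanism
  fam <- sd$truth$family[match(pt$accession_a, sd$truth$protein)]
  famb <- sd$truth$family[match(pt$accession_b, sd$truth$protein)]
  expect_equal(same, !is.na(fam) & !is.na(famb) & fam == famb)
  # same-mechanism pairs sit inside the configured identity band
  expect_true(all(pt$identity[same] >= sd$config$identity_band[1] - 0.02))
  # missing sequences are skipped and reported
  pt2 <- pair_table(sd$dataset, sd$store[-1])
  expect_equal(attr(pt2, "skipped"), sd$dataset$ids[1])
  expect_equal(nrow(pt2), choose(n - 1, 2))
})
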