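#' Euclidean distance between attribute vectors
#'
#' On binary signature vectors this is `sqrt(x)` for two instances differing
#' in `x` attributes: 0 for identical signature sets, 1 for a single
#' differing signature, and so on.
#'
#' @param u,v Numeric vectors over the same attribute space (same length and,
#'   if named, the same names in the same order).
#' @return Non-negative distance.
#' @export
euclidean_distance <- function(u, v) {
  check_same_space(u, v)
  sqrt(sum((u - v)^2))
}

#' Jaccard distance between binary attribute vectors
#'
#' One minus the ratio of shared to pooled active attributes. Two all-zero
#' vectors are at distance 0 by convention.
#'
#' @param u,v Binary (0/1) vectors over the same attribute space.
#' @return Distance in `[0, 1]`.
#' @export
jaccard_distance <- function(u, v) {
  check_same_space(u, v)
  if (!all(u %in% c(0, 1)) || !all(v %in% c(0, 1))) {
    stop("Jaccard distance is only defined for binary attribute vectors")
  }
  a <- which(u != 0)
  b <- which(v != 0)
  un <- length(union(a, b))
  if (un == 0) return(0)
  1 - length(intersect(a, b)) / un
}

check_same_space <- function(u, v) {
  if (length(u) != length(v)) {
    stop("attribute spaces differ in dimension (", length(u), " vs ",
         length(v), ")")
  }
  if (!is.null(names(u)) && !is.null(names(v)) && !identical(names(u), names(v))) {
    stop("attribute spaces differ in attribute names/order")
  }
  invisible(TRUE)
}

# All-pairs distances between the rows of two (sparse) matrices.
# Returned dense: callers operate on modest instance counts.
dist_matrix <- function(A, B, distance = c("euclidean", "jaccard"),
                        kind = NULL) {
  distance <- match.arg(distance)
  if (ncol(A) != ncol(B)) stop("attribute spaces differ in dimension")
  if (distance == "euclidean") {
    d2 <- outer(Matrix::rowSums(A * A), Matrix::rowSums(B * B), "+") -
      2 * as.matrix(Matrix::tcrossprod(A, B))
    d2[d2 < 0] <- 0
    sqrt(d2)
  } else {
    if (!is.null(kind) && any(kind != "binary")) {
      stop("Jaccard distance is only defined for binary attribute vectors")
    }
    av <- A@x
    bv <- B@x
    if ((length(av) && !all(av %in% c(0, 1))) ||
        (length(bv) && !all(bv %in% c(0, 1)))) {
      stop("Jaccard distance is only defined for binary attribute vectors")
    }
    inter <- as.matrix(Matrix::tcrossprod(A, B))
    un <- outer(Matrix::rowSums(A), Matrix::rowSums(B), "+") - inter
    d <- 1 - inter / un
    d[un == 0] <- 0
    d
  }
}
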