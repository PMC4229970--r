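#' Construct a multi-label dataset
#'
#' The central container of the package: a set of protein instances, each with
#' a sparse attribute vector and a (possibly empty) set of mechanism labels.
#' Attributes are either `"binary"` (signature presence/absence, values in
#' \{0, 1\}) or `"numeric"` (profile attributes such as per-mechanism distances
#' or identities). The label space is the universe `L` over which multi-label
#' metrics are computed; instances flagged as padding are the "empty" anchor
#' instances used only during training, never as test cases.
#'
#' @param ids Character vector of unique instance identifiers (protein
#'   accessions).
#' @param X Attribute matrix (instances x attributes), dense or sparse; stored
#'   internally as a `CsparseMatrix`. Column names are the attribute names.
#' @param labels List of character vectors, one per instance; each element is
#'   the instance's label set (may be empty).
#' @param label_space Character vector of all label identifiers. Defaults to
#'   the sorted union of instance labels.
#' @param attr_kind Character vector (`"binary"` or `"numeric"`), one entry per
#'   attribute column. Defaults to `"binary"` for all columns.
#' @param padding Logical vector flagging padding (empty anchor) instances.
#'
#' @return An object of class `ml_dataset` with fields `ids`, `X`,
#'   `attr_kind`, `labels`, `label_space`, `padding`.
#' @seealso [read_mulan()], [build_dataset()], [add_empty_instances()]
#' @export
ml_dataset <- function(ids, X, labels, label_space = NULL, attr_kind = NULL,
                       padding = NULL) {
  ids <- as.character(ids)
  X <- methods::as(methods::as(Matrix::Matrix(X, sparse = TRUE), "generalMatrix"),
                   "CsparseMatrix")
  if (is.null(colnames(X))) {
    colnames(X) <- sprintf("attr_%d", seq_len(ncol(X)))
  }
  rownames(X) <- ids
  labels <- unname(lapply(labels, as.character))
  if (is.null(label_space)) {
    label_space <- sort(unique(unlist(labels)))
  }
  if (is.null(attr_kind)) attr_kind <- rep("binary", ncol(X))
  if (is.null(padding)) padding <- rep(FALSE, length(ids))
  obj <- structure(
    list(ids = ids, X = X, attr_kind = attr_kind, labels = labels,
         label_space = as.character(label_space), padding = padding),
    class = "ml_dataset")
  validate_ml_dataset(obj)
  obj
}

#' Validate an `ml_dataset`
#'
#' Checks the container invariants: unique instance ids, matching dimensions,
#' every instance label inside the label space, and binary columns holding only
#' 0/1 values.
#'
#' @param d An `ml_dataset`.
#' @return `d`, invisibly; errors on violation.
#' @export
validate_ml_dataset <- function(d) {
  stopifnot(inherits(d, "ml_dataset"))
  n <- length(d$ids)
  if (anyDuplicated(d$ids)) stop("instance ids must be unique")
  if (nrow(d$X) != n) stop("attribute matrix row count does not match ids")
  if (length(d$labels) != n) stop("labels list length does not match ids")
  if (length(d$padding) != n) stop("padding flag length does not match ids")
  if (length(d$attr_kind) != ncol(d$X)) {
    stop("attr_kind length does not match attribute count")
  }
  if (!all(d$attr_kind %in% c("binary", "numeric"))) {
    stop("attr_kind entries must be 'binary' or 'numeric'")
  }
  if (anyDuplicated(colnames(d$X))) stop("attribute names must be unique")
  bad <- setdiff(unique(unlist(d$labels)), d$label_space)
  if (length(bad)) {
    stop("instance labels outside label_space: ", paste(bad, collapse = ", "))
  }
  bin <- which(d$attr_kind == "binary")
  if (length(bin)) {
    v <- d$X[, bin, drop = FALSE]@x
    if (length(v) && !all(v %in% c(0, 1))) {
      stop("binary attribute with value outside {0,1}")
    }
  }
  invisible(d)
}

#' @export
print.ml_dataset <- function(x, ...) {
  cat(sprintf(
    "ml_dataset: %d instances (%d padding), %d attributes (%d binary, %d numeric), %d labels\n",
    length(x$ids), sum(x$padding), ncol(x$X),
    sum(x$attr_kind == "binary"), sum(x$attr_kind == "numeric"),
    length(x$label_space)))
  invisible(x)
}

#' Number of instances in a dataset
#' @param d An `ml_dataset`.
#' @param real_only Count only non-padding instances?
#' @return Integer count.
#' @export
n_instances <- function(d, real_only = FALSE) {
  if (real_only) sum(!d$padding) else length(d$ids)
}

#' Subset a multi-label dataset by instance
#'
#' @param x An `ml_dataset`.
#' @param i Integer, logical or character (id) index.
#' @param ... Unused.
#' @return An `ml_dataset` with the selected instances; the attribute and
#'   label spaces are kept unchanged.
#' @export
`[.ml_dataset` <- function(x, i, ...) {
  if (is.character(i)) i <- match(i, x$ids)
  if (anyNA(i)) stop("unknown instance id in subset")
  ml_dataset(x$ids[i], x$X[i, , drop = FALSE], x$labels[i],
             label_space = x$label_space, attr_kind = x$attr_kind,
             padding = x$padding[i])
}

#' Build a dataset from annotation tables
#'
#' Constructs the binary signature-presence matrix from two long tables: one
#' mapping proteins to signatures (e.g. InterPro identifiers or CSA site
#' matches) and one mapping proteins to mechanism labels. Attribute `j` of a
#' protein is 1 iff the protein carries signature `j`. Proteins appearing only
#' in the label table get an all-zero attribute row; duplicate
#' (protein, signature) rows are collapsed.
#'
#' @param annotations Data frame with columns `protein`, `signature`.
#' @param labels Data frame with columns `protein`, `label`; may have zero rows
#'   (a fully unlabeled, negative-style set).
#' @return An `ml_dataset` whose attribute space is the sorted set of distinct
#'   signatures.
#' @export
build_dataset <- function(annotations, labels = NULL) {
  stopifnot(is.data.frame(annotations),
            all(c("protein", "signature") %in% names(annotations)))
  if (is.null(labels)) {
    labels <- data.frame(protein = character(), label = character())
  }
  stopifnot(is.data.frame(labels), all(c("protein", "label") %in% names(labels)))
  if (nrow(annotations) == 0 && nrow(labels) == 0) {
    stop("both annotation and label tables are empty")
  }
  prot <- unique(c(as.character(annotations$protein), as.character(labels$protein)))
  sigs <- sort(unique(as.character(annotations$signature)))
  i <- match(as.character(annotations$protein), prot)
  j <- match(as.character(annotations$signature), sigs)
  X <- Matrix::sparseMatrix(i = i, j = j, x = 1, dims = c(length(prot), length(sigs)),
                            dimnames = list(prot, sigs), use.last.ij = TRUE)
  lab <- split(as.character(labels$label), factor(as.character(labels$protein), levels = prot))
  lab <- lapply(lab, unique)
  ml_dataset(prot, X, lab[prot])
}

#' Refine mechanism labels with subunit roles
#'
#' Replaces, per protein, an original 5-character mechanism code with a refined
#' mechanism + subunit label (e.g. `M0314` carried by an anthranilate synthase
#' component I chain becomes `M0314_component_I`). Proteins and labels not
#' covered by the map are left unchanged. The original annotation is
#' recoverable with [truncate_labels()].
#'
#' @param dataset An `ml_dataset`.
#' @param map Data frame with columns `original`, `protein`, `split`: the
#'   original label, the protein accession, and the refined label (which must
#'   begin with the original code).
#' @return An `ml_dataset` with refined labels and an updated label space;
#'   the instance count is unchanged.
#' @export
split_labels <- function(dataset, map) {
  stopifnot(inherits(dataset, "ml_dataset"), is.data.frame(map),
            all(c("original", "protein", "split") %in% names(map)))
  if (nrow(map) == 0) return(dataset)
  map$original <- as.character(map$original)
  map$protein <- as.character(map$protein)
  map$split <- as.character(map$split)
  if (!all(startsWith(map$split, substr(map$original, 1, 5)))) {
    stop("split label does not begin with its original 5-character code")
  }
  labels <- dataset$labels
  names(labels) <- dataset$ids
  for (r in seq_len(nrow(map))) {
    p <- map$protein[r]
    if (!p %in% dataset$ids) {
      stop("split map names unknown protein: ", p)
    }
    cur <- labels[[p]]
    if (!map$original[r] %in% cur) {
      stop(sprintf("protein %s does not carry label %s", p, map$original[r]))
    }
    labels[[p]] <- unique(c(setdiff(cur, map$original[r]), map$split[r]))
  }
  # drop original codes whose every carrier was remapped; keep everything else
  kept <- union(setdiff(dataset$label_space, map$original), unique(unlist(labels)))
  ml_dataset(dataset$ids, dataset$X, unname(labels),
             label_space = sort(kept), attr_kind = dataset$attr_kind,
             padding = dataset$padding)
}

#' Truncate refined labels back to 5-character mechanism codes
#'
#' Discards any text beyond the fifth character of every label, collapsing
#' duplicates per instance to a set — the inverse of [split_labels()] at the
#' 5-character level. Labels are validated against the mechanism code
#' convention (`M` followed by four digits).
#'
#' @param dataset An `ml_dataset`.
#' @return An `ml_dataset` with truncated labels.
#' @export
truncate_labels <- function(dataset) {
  stopifnot(inherits(dataset, "ml_dataset"))
  all_labs <- unique(c(unlist(dataset$labels), dataset$label_space))
  if (any(nchar(all_labs) < 5)) {
    stop("label shorter than 5 characters cannot be truncated")
  }
  if (length(all_labs) && !all(grepl("^M[0-9]{4}", all_labs))) {
    stop("label does not follow the mechanism code convention 'M' + 4 digits")
  }
  labels <- lapply(dataset$labels, function(l) unique(substr(l, 1, 5)))
  ml_dataset(dataset$ids, dataset$X, labels,
             label_space = sort(unique(substr(dataset$label_space, 1, 5))),
             attr_kind = dataset$attr_kind, padding = dataset$padding)
}

#' Append empty anchor instances
#'
#' Adds `count` instances with no attributes and no labels. In
#' nearest-neighbour prediction a query sharing no attribute with any real
#' training instance would otherwise gravitate towards the training instance
#' with the fewest attributes; an empty anchor sits at distance
#' `sqrt(q)` from a query with `q` active attributes and yields an empty
#' predicted label set instead. Anchors get reserved ids (`__EMPTY_1`, ...),
#' are flagged as padding, and are excluded from test folds and metric
#' denominators by the evaluation drivers.
#'
#' @param dataset An `ml_dataset`.
#' @param count Number of instances to append (>= 0).
#' @return The padded `ml_dataset`.
#' @export
add_empty_instances <- function(dataset, count) {
  stopifnot(inherits(dataset, "ml_dataset"), count >= 0)
  if (count == 0) return(dataset)
  start <- sum(dataset$padding)
  ids <- sprintf("__EMPTY_%d", start + seq_len(count))
  Z <- Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                            dims = c(count, ncol(dataset$X)),
                            dimnames = list(ids, colnames(dataset$X)))
  ml_dataset(c(dataset$ids, ids), rbind(dataset$X, Z),
             c(dataset$labels, rep(list(character()), count)),
             label_space = dataset$label_space, attr_kind = dataset$attr_kind,
             padding = c(dataset$padding, rep(TRUE, count)))
}

#' Re-index a dataset onto a given attribute space
#'
#' Returns a dataset whose attribute columns follow `space`; attributes absent
#' from the input are added as all-zero columns. Attributes of the input not in
#' `space` must be absent or an error is raised (no silent dropping).
#'
#' @param dataset An `ml_dataset`.
#' @param space Character vector of attribute names.
#' @param kind Attribute kinds for `space` (recycled from the dataset where
#'   known, `"binary"` for new columns unless given).
#' @return An `ml_dataset` over `space`.
#' @export
align_attributes <- function(dataset, space, kind = NULL) {
  stopifnot(inherits(dataset, "ml_dataset"))
  extra <- setdiff(colnames(dataset$X), space)
  if (length(extra)) {
    stop("dataset has attributes outside the target space: ",
         paste(utils::head(extra, 5), collapse = ", "))
  }
  idx <- match(space, colnames(dataset$X))
  n <- length(dataset$ids)
  Xnew <- Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                               dims = c(n, length(space)),
                               dimnames = list(dataset$ids, space))
  have <- which(!is.na(idx))
  if (length(have)) Xnew[, have] <- dataset$X[, idx[have], drop = FALSE]
  if (is.null(kind)) {
    kind <- rep("binary", length(space))
    kind[have] <- dataset$attr_kind[idx[have]]
  }
  ml_dataset(dataset$ids, Xnew, dataset$labels, label_space = dataset$label_space,
             attr_kind = kind, padding = dataset$padding)
}

# shared union-space alignment used by train/test evaluation
union_align <- function(train, test) {
  space <- union(colnames(train$X), colnames(test$X))
  kind <- rep("binary", length(space))
  kind[match(colnames(train$X), space)] <- train$attr_kind
  kind[match(colnames(test$X), space)] <- test$attr_kind
  list(train = align_attributes(train, space, kind),
       test = align_attributes(test, space, kind))
}
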