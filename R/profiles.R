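# Per-mechanism profile attributes: for a query protein, one value per
# mechanism m in the training label space — either the minimum signature-space
# Euclidean distance to any training carrier of m, or the maximum global
# sequence identity to any carrier. A mechanism that has no carriers in the
# visible training fold (possible under leave-one-out) takes a sentinel that
# can never win a nearest-neighbour comparison: a large finite distance for
# the minimum-distance profile, 0 for the maximum-identity profile.

#' Sentinel distance for mechanisms without training carriers
#' @export
NO_CARRIER_DISTANCE <- 1e6

#' Minimum-Euclidean-distance profile of a query protein
#'
#' For each mechanism `m` in the training label space, the minimum Euclidean
#' distance (in the signature attribute space) between the query vector and
#' any training protein carrying `m`.
#'
#' @param query Numeric attribute vector over the training attribute space.
#' @param train An `ml_dataset` providing carriers per mechanism.
#' @return Named numeric vector over `train$label_space` (the profile
#'   vector); mechanisms without carriers take [NO_CARRIER_DISTANCE].
#' @export
min_euclidean_profile <- function(query, train) {
  stopifnot(inherits(train, "ml_dataset"))
  if (length(query) != ncol(train$X)) {
    stop("query vector does not match the training attribute space")
  }
  Q <- Matrix::Matrix(matrix(query, nrow = 1), sparse = TRUE)
  d <- dist_matrix(methods::as(methods::as(Q, "generalMatrix"), "CsparseMatrix"),
                   train$X, "euclidean")[1, ]
  vapply(train$label_space, function(m) {
    carriers <- which(vapply(train$labels, function(l) m %in% l, TRUE))
    if (length(carriers) == 0) NO_CARRIER_DISTANCE else min(d[carriers])
  }, numeric(1))
}

#' Maximum-sequence-identity profile of a query protein
#'
#' For each mechanism `m` in the training label space, the maximum global
#' alignment identity between the query sequence and any training carrier
#' of `m`. A mechanism without carriers takes 0.
#'
#' @param query_seq Amino-acid sequence of the query.
#' @param train An `ml_dataset`.
#' @param store Named character vector of sequences covering all carriers.
#' @param params [alignment_params()].
#' @return Named numeric vector over `train$label_space`, values in `[0, 1]`.
#' @export
max_identity_profile <- function(query_seq, train, store,
                                 params = alignment_params()) {
  stopifnot(inherits(train, "ml_dataset"))
  carriers_of <- lapply(train$label_space, function(m) {
    train$ids[vapply(train$labels, function(l) m %in% l, TRUE)]
  })
  need <- unique(unlist(carriers_of))
  miss <- setdiff(need, names(store))
  if (length(miss)) {
    stop("missing sequence(s) for training carrier(s): ",
         paste(utils::head(miss, 5), collapse = ", "))
  }
  ident <- vapply(need, function(a) {
    pairwise_identity(query_seq, store[[a]], params)
  }, numeric(1))
  names(ident) <- need
  out <- vapply(carriers_of, function(cc) {
    if (length(cc) == 0) 0 else max(ident[cc])
  }, numeric(1))
  names(out) <- train$label_space
  out
}

#' Build a profile attribute dataset
#'
#' Replaces each instance's signature attributes by its per-mechanism profile
#' vector — minimum Euclidean distance (`"min_euclid"`), maximum sequence
#' identity (`"max_identity"`), or both concatenated. Profiles are computed
#' leave-one-out by default (each instance profiled against all *other*
#' instances) so that a later cross-validation of the profile dataset never
#' sees an instance's own distance-0/identity-1 entry. Padding instances are
#' dropped; labels are carried over unchanged.
#'
#' @param dataset An `ml_dataset` with binary signature attributes.
#' @param type `"min_euclid"`, `"max_identity"`, or `"both"`.
#' @param store Sequence store (required for identity profiles).
#' @param params [alignment_params()].
#' @param leave_one_out Profile each instance against all others (default)
#'   rather than against the full set including itself.
#' @return An `ml_dataset` with numeric profile attributes named
#'   `dmin_<label>` / `idmax_<label>`.
#' @export
profile_dataset <- function(dataset, type = c("min_euclid", "max_identity", "both"),
                            store = NULL, params = alignment_params(),
                            leave_one_out = TRUE) {
  type <- match.arg(type)
  stopifnot(inherits(dataset, "ml_dataset"))
  real <- dataset[which(!dataset$padding)]
  n <- length(real$ids)
  labs <- real$label_space
  carrier_mask <- vapply(labs, function(m) {
    vapply(real$labels, function(l) m %in% l, TRUE)
  }, logical(n))
  if (is.null(dim(carrier_mask))) carrier_mask <- matrix(carrier_mask, nrow = n)

  blocks <- list()
  if (type %in% c("min_euclid", "both")) {
    D <- dist_matrix(real$X, real$X, "euclidean")
    if (leave_one_out) diag(D) <- Inf
    P <- vapply(seq_along(labs), function(j) {
      idx <- which(carrier_mask[, j])
      vapply(seq_len(n), function(i) {
        cand <- if (leave_one_out) setdiff(idx, i) else idx
        if (length(cand) == 0) NO_CARRIER_DISTANCE else min(D[i, cand])
      }, numeric(1))
    }, numeric(n))
    if (is.null(dim(P))) P <- matrix(P, nrow = n)
    colnames(P) <- paste0("dmin_", labs)
    blocks$min_euclid <- P
  }
  if (type %in% c("max_identity", "both")) {
    if (is.null(store)) stop("an identity profile needs a sequence store")
    M <- identity_matrix(store, real$ids, params)
    P <- vapply(seq_along(labs), function(j) {
      idx <- which(carrier_mask[, j])
      vapply(seq_len(n), function(i) {
        cand <- if (leave_one_out) setdiff(idx, i) else idx
        if (length(cand) == 0) 0 else max(M[i, cand])
      }, numeric(1))
    }, numeric(n))
    if (is.null(dim(P))) P <- matrix(P, nrow = n)
    colnames(P) <- paste0("idmax_", labs)
    blocks$max_identity <- P
  }
  Xp <- do.call(cbind, unname(blocks))
  ml_dataset(real$ids, Xp, real$labels, label_space = labs,
             attr_kind = rep("numeric", ncol(Xp)))
}

#' Combine attribute sets over the same instances
#'
#' Column-wise concatenation of several datasets describing the same instances
#' (e.g. InterPro + CSA signatures, or identity + distance profiles).
#' Attribute names must be disjoint across sets, or a `namespaces` prefix is
#' applied; labels are taken from the first set and must agree across all
#' sets.
#'
#' @param sets List of `ml_dataset` objects with identical instance id order.
#' @param namespaces Optional character vector (one per set) prefixed as
#'   `"<ns>."` to every attribute name of that set.
#' @return The combined `ml_dataset`.
#' @export
combine_attribute_sets <- function(sets, namespaces = NULL) {
  stopifnot(is.list(sets), length(sets) >= 1)
  lapply(sets, function(s) stopifnot(inherits(s, "ml_dataset")))
  first <- sets[[1]]
  for (s in sets[-1]) {
    if (!identical(s$ids, first$ids)) {
      stop("attribute sets describe different instances (or a different order)")
    }
    agree <- mapply(setequal, s$labels, first$labels)
    if (!all(agree)) {
      stop("label disagreement between attribute sets at instance: ",
           first$ids[which(!agree)[1]])
    }
  }
  Xs <- lapply(seq_along(sets), function(k) {
    X <- sets[[k]]$X
    if (!is.null(namespaces)) {
      colnames(X) <- paste0(namespaces[k], ".", colnames(X))
    }
    X
  })
  nm <- unlist(lapply(Xs, colnames))
  if (anyDuplicated(nm)) {
    stop("attribute names clash across sets; pass namespaces= to prefix them")
  }
  ml_dataset(first$ids, do.call(cbind, Xs), first$labels,
             label_space = sort(unique(unlist(lapply(sets, `[[`, "label_space")))),
             attr_kind = unlist(lapply(sets, `[[`, "attr_kind")),
             padding = first$padding)
}
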