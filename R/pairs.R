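#' All-pairs identity / signature-distance table
#'
#' For every unordered pair of real (non-padding) instances, computes the
#' global sequence identity, the Euclidean distance between the two signature
#' vectors, and whether the two proteins share at least one mechanism label.
#' This is the raw material of the identity-vs-distance scatter in which
#' same-mechanism couples form a low-distance band, and of the line-separator
#' baseline ([line_classify()], [line_sweep()]).
#'
#' Pairs with a missing sequence are omitted and the offending accessions
#' recorded in the `"skipped"` attribute of the result.
#'
#' @param dataset An `ml_dataset` with binary signature attributes.
#' @param store Named character vector of sequences.
#' @param params [alignment_params()].
#' @return Data frame with columns `accession_a`, `accession_b` (lexically
#'   ordered within each pair), `identity`, `euclid`, `same_mechanism`.
#' @export
pair_table <- function(dataset, store, params = alignment_params()) {
  stopifnot(inherits(dataset, "ml_dataset"))
  real <- dataset[which(!dataset$padding)]
  have <- real$ids %in% names(store)
  skipped <- real$ids[!have]
  real <- real[which(have)]
  n <- length(real$ids)
  if (n < 2) stop("need at least two instances with sequences")
  D <- dist_matrix(real$X, real$X, "euclidean")
  idx <- utils::combn(n, 2)
  a <- real$ids[idx[1, ]]
  b <- real$ids[idx[2, ]]
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  ident <- vapply(seq_len(ncol(idx)), function(k) {
    pairwise_identity(store[[real$ids[idx[1, k]]]],
                      store[[real$ids[idx[2, k]]]], params)
  }, numeric(1))
  same <- vapply(seq_len(ncol(idx)), function(k) {
    length(intersect(real$labels[[idx[1, k]]], real$labels[[idx[2, k]]])) > 0
  }, logical(1))
  out <- data.frame(accession_a = a, accession_b = b, identity = ident,
                    euclid = D[t(idx)], same_mechanism = same,
                    stringsAsFactors = FALSE)
  attr(out, "skipped") <- skipped
  out
}
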