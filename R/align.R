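#' Read a substitution matrix in EMBOSS/NCBI text format
#'
#' Parses the standard scoring-matrix text layout: `#` comment lines, a header
#' row of column letters, then one row per residue. The package bundles
#' `EBLOSUM62.txt` (the BLOSUM62 matrix in half-bit units, with B/Z/X/`*`
#' rows), the default matrix of the EMBOSS global aligner.
#'
#' @param path Path to the matrix file.
#' @return Integer matrix with residue row/column names.
#' @export
read_substitution_matrix <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines[!grepl("^\\s*#", lines)])
  lines <- lines[nzchar(lines)]
  cols <- strsplit(lines[1], "\\s+")[[1]]
  rows <- strsplit(lines[-1], "\\s+")
  m <- t(vapply(rows, function(r) as.integer(r[-1]), integer(length(cols))))
  rownames(m) <- vapply(rows, `[[`, "", 1)
  colnames(m) <- cols
  if (!identical(sort(rownames(m)), sort(colnames(m)))) {
    stop("substitution matrix rows and columns name different residue sets")
  }
  m
}

#' Global alignment parameters
#'
#' Defaults follow the EMBOSS Needleman-Wunsch defaults: the EBLOSUM62
#' substitution matrix with gap opening penalty 10 and gap extension penalty
#' 0.5 (a gap of length L costs `10 + 0.5 * L`).
#'
#' @param matrix Substitution matrix: a numeric matrix, or the name
#'   `"EBLOSUM62"` for the bundled matrix.
#' @param gap_open Gap opening penalty (> 0).
#' @param gap_extend Gap extension penalty per residue (> 0).
#' @return A list of class `alignment_params`.
#' @export
alignment_params <- function(matrix = "EBLOSUM62", gap_open = 10,
                             gap_extend = 0.5) {
  if (is.character(matrix)) {
    if (!identical(matrix, "EBLOSUM62")) {
      stop("unknown bundled matrix: ", matrix)
    }
    path <- system.file("extdata", "EBLOSUM62.txt", package = "mechknn")
    matrix <- read_substitution_matrix(path)
  }
  stopifnot(is.matrix(matrix), gap_open > 0, gap_extend > 0)
  structure(list(matrix = matrix, gap_open = gap_open, gap_extend = gap_extend),
            class = "alignment_params")
}

.clean_seq <- function(seq, letters) {
  seq <- toupper(seq)
  if (!nzchar(seq)) stop("empty sequence passed to alignment")
  chars <- strsplit(seq, "")[[1]]
  chars[!chars %in% letters] <- "X"   # unknown residues scored via wildcard row
  paste(chars, collapse = "")
}

#' Global pairwise sequence identity
#'
#' Aligns two amino-acid sequences end to end (Needleman-Wunsch with affine
#' gaps) and returns the fraction of identical aligned positions over the full
#' alignment length, gap columns included — the EMBOSS "Identity" convention.
#' The value spans 0 (no residue aligned identically) to 1 (identical
#' sequences). Case-insensitive; residues outside the matrix alphabet are
#' scored through the `X` wildcard row.
#'
#' @param seq_a,seq_b Amino-acid sequences (character scalars).
#' @param params An [alignment_params()] object.
#' @return Identity fraction in `[0, 1]`.
#' @export
pairwise_identity <- function(seq_a, seq_b, params = alignment_params()) {
  stopifnot(inherits(params, "alignment_params"))
  letters <- rownames(params$matrix)
  seq_a <- .clean_seq(seq_a, letters)
  seq_b <- .clean_seq(seq_b, letters)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(seq_a), Biostrings::AAString(seq_b),
    type = "global", substitutionMatrix = params$matrix,
    gapOpening = params$gap_open, gapExtension = params$gap_extend)
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  pb <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  sum(pa == pb & pa != "-") / length(pa)
}

# identity matrix over a set of accessions; symmetric, diagonal 1
identity_matrix <- function(store, ids, params = alignment_params()) {
  miss <- setdiff(ids, names(store))
  if (length(miss)) {
    stop("missing sequence(s) for: ", paste(utils::head(miss, 5), collapse = ", "))
  }
  n <- length(ids)
  m <- diag(1, n)
  dimnames(m) <- list(ids, ids)
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        m[i, j] <- m[j, i] <- pairwise_identity(store[[ids[i]]],
                                                store[[ids[j]]], params)
      }
    }
  }
  m
}
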