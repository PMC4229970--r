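#' Read protein sequences from FASTA
#'
#' Sequences are returned as a named character vector (a sequence store)
#' keyed by accession. The accession is the first whitespace-delimited header
#' token; UniProt-style `sp|ACC|NAME` / `tr|ACC|NAME` tokens are additionally
#' reduced to `ACC`, since real inputs mix plain and UniProt headers.
#' Sequences are uppercased.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of amino-acid sequences.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0) stop("FASTA file contains no records: ", path)
  seqs <- toupper(as.character(set))
  acc <- vapply(strsplit(names(set), "[ \t]"), `[[`, "", 1)
  uni <- grepl("^(sp|tr)\\|", acc)
  acc[uni] <- vapply(strsplit(acc[uni], "\\|"), `[[`, "", 2)
  if (any(!nzchar(seqs))) {
    stop("empty sequence record: ", acc[which(!nzchar(seqs))[1]])
  }
  if (anyDuplicated(acc)) stop("duplicate accession in FASTA: ",
                               acc[duplicated(acc)][1])
  names(seqs) <- acc
  seqs
}

#' Write a sequence store to FASTA
#'
#' @param store Named character vector of sequences.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(store, path) {
  if (length(store) == 0 || is.null(names(store))) {
    stop("sequence store must be a non-empty named character vector")
  }
  set <- Biostrings::AAStringSet(store)
  Biostrings::writeXStringSet(set, path, width = 60)
  invisible(path)
}
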