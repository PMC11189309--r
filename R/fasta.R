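# FASTA IO for protein sequence sets (thin wrappers over Biostrings).

#' Read protein sequences from a FASTA file
#'
#' @param path FASTA path.
#' @return named character vector of sequences.
#' @export
read_proteome_fasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' Write protein sequences to a FASTA file
#'
#' @param sequences named character vector.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_proteome_fasta <- function(sequences, path) {
  Biostrings::writeXStringSet(Biostrings::AAStringSet(sequences), path)
  invisible(path)
}
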