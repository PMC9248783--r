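#' Read sequences from a FASTA file
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()] returning the
#' tidy template shape the rest of the package consumes.
#'
#' @param path FASTA file path.
#' @return Tibble with columns `label`, `sequence`.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  tibble(label = names(ss), sequence = unname(as.character(ss)))
}

#' Write sequences to a FASTA file
#'
#' @param seqs Tibble with columns `label`, `sequence` (or named
#'   character vector).
#' @param path Output path.
#' @return Invisibly `path`.
#' @export
write_fasta <- function(seqs, path) {
  tt <- as_template_tbl(seqs)
  ss <- Biostrings::DNAStringSet(setNames(tt$sequence, tt$label))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
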