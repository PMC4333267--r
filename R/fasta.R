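#' Read reference sequences from FASTA
#'
#' Thin wrapper around [Biostrings::readDNAStringSet()] returning the
#' in-memory representation used throughout the package: a named
#' character vector of chromosome sequences. Header descriptions after
#' the first whitespace are dropped.
#'
#' @param path FASTA path.
#' @return Named character vector.
#' @export
read_reference <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write reference sequences as FASTA
#'
#' @param reference named character vector of sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_reference <- function(reference, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(reference), filepath = path, width = 70L)
  invisible(path)
}
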