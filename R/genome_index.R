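#' Genome index: ordered chromosome names and lengths
#'
#' The genome index is the partitioning substrate: an ordered table of
#' `(name, length)` pairs, as found in a FASTA `.fai` companion index.
#' The row order is stable and defines the global chromosome sort order
#' used everywhere downstream (SAM headers, canonical record sorts, VCF
#' contig lines).
#'
#' Chromosome lengths are stored as doubles so that genomes larger than
#' `.Machine$integer.max` (e.g. a 3 Gbp chromosome) are representable.
#'
#' @param names character vector of unique chromosome identifiers.
#' @param lengths numeric vector of chromosome lengths in base pairs,
#'   all `>= 1`.
#' @return An object of class `genome_index`: a data.frame with columns
#'   `name` and `length`.
#' @examples
#' genome_index(c("chr1", "chr2"), c(100000, 50000))
#' @export
genome_index <- function(names, lengths) {
  names <- as.character(names)
  lengths <- as.numeric(lengths)
  if (length(names) == 0L) {
    stop("genome index must contain at least one sequence", call. = FALSE)
  }
  if (length(names) != length(lengths)) {
    stop("'names' and 'lengths' must have equal length", call. = FALSE)
  }
  if (anyDuplicated(names)) {
    stop("chromosome names must be unique", call. = FALSE)
  }
  if (any(!is.finite(lengths)) || any(lengths < 1) ||
      any(lengths != floor(lengths))) {
    stop("chromosome lengths must be positive integers", call. = FALSE)
  }
  out <- data.frame(name = names, length = lengths,
                    stringsAsFactors = FALSE)
  class(out) <- c("genome_index", "data.frame")
  out
}

#' @export
print.genome_index <- function(x, ...) {
  cat(sprintf("<genome_index> %d sequence(s), %s bp total\n",
              nrow(x), format(sum(x$length), big.mark = ",",
                              scientific = FALSE)))
  print.data.frame(utils::head(as.data.frame(x), 10), ...)
  if (nrow(x) > 10) cat(sprintf("... and %d more\n", nrow(x) - 10L))
  invisible(x)
}

#' Read a genome index from FASTA-index-style text
#'
#' Reads a whitespace-separated text file whose first two columns are
#' sequence name and length (the layout of `samtools faidx` output;
#' extra columns are ignored). Lines starting with `#` are skipped.
#'
#' @param path path to the index file.
#' @return A [genome_index()].
#' @export
read_genome_index <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (length(lines) == 0L) {
    stop("empty genome index file: ", path, call. = FALSE)
  }
  parts <- strsplit(trimws(lines), "[ \t]+")
  bad <- which(lengths(parts) < 2L)
  if (length(bad)) {
    stop(sprintf("malformed genome index line %d in %s", bad[1], path),
         call. = FALSE)
  }
  genome_index(vapply(parts, `[[`, "", 1L),
               as.numeric(vapply(parts, `[[`, "", 2L)))
}

#' Write a genome index as two-column text
#'
#' @param index a [genome_index()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genome_index <- function(index, path) {
  stopifnot(inherits(index, "genome_index"))
  writeLines(sprintf("%s\t%s", index$name, format_bp(index$length)), path)
  invisible(path)
}

#' Build a genome index from in-memory reference sequences
#'
#' @param reference named character vector of chromosome sequences.
#' @return A [genome_index()] in the order of `reference`.
#' @export
index_from_reference <- function(reference) {
  if (is.null(names(reference)) || any(!nzchar(names(reference)))) {
    stop("reference sequences must be named", call. = FALSE)
  }
  genome_index(names(reference), nchar(reference))
}

# integer-style formatting for coordinates that may exceed 32-bit range
format_bp <- function(x) {
  sprintf("%.0f", x)
}
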