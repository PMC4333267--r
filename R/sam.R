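#' @import data.table
#' @importFrom stats rnorm rbinom pbinom runif
#' @importFrom utils head
NULL

# SAM bit-flags
FLAG_PAIRED <- 0x1L
FLAG_PROPER <- 0x2L
FLAG_UNMAPPED <- 0x4L
FLAG_MATE_UNMAPPED <- 0x8L
FLAG_REVERSE <- 0x10L
FLAG_MATE_REVERSE <- 0x20L
FLAG_FIRST <- 0x40L
FLAG_SECOND <- 0x80L
FLAG_SECONDARY <- 0x100L
FLAG_DUPLICATE <- 0x400L
FLAG_SUPPLEMENTARY <- 0x800L

#' Test SAM flag bits
#'
#' Vectorized accessors for the SAM flag bits the pipeline cares about.
#'
#' @param flag integer vector of SAM flags.
#' @return Logical vector.
#' @name sam-flags
NULL

#' @rdname sam-flags
#' @export
is_unmapped <- function(flag) bitwAnd(flag, FLAG_UNMAPPED) != 0L

#' @rdname sam-flags
#' @export
is_mate_unmapped <- function(flag) bitwAnd(flag, FLAG_MATE_UNMAPPED) != 0L

#' @rdname sam-flags
#' @export
is_reverse <- function(flag) bitwAnd(flag, FLAG_REVERSE) != 0L

#' @rdname sam-flags
#' @export
is_first_of_pair <- function(flag) bitwAnd(flag, FLAG_FIRST) != 0L

#' @rdname sam-flags
#' @export
is_second_of_pair <- function(flag) bitwAnd(flag, FLAG_SECOND) != 0L

#' @rdname sam-flags
#' @export
is_primary <- function(flag) {
  bitwAnd(flag, bitwOr(FLAG_SECONDARY, FLAG_SUPPLEMENTARY)) == 0L
}

#' @rdname sam-flags
#' @export
is_duplicate_flagged <- function(flag) bitwAnd(flag, FLAG_DUPLICATE) != 0L

SAM_COLS <- c("qname", "flag", "rname", "pos", "mapq", "cigar",
              "rnext", "pnext", "tlen", "seq", "qual", "tags")

#' Construct an aligned-read table
#'
#' Records are held as a data.table with the eleven mandatory SAM
#' fields plus a `tags` column (the tab-joined optional fields, `""`
#' when absent). `rnext` always stores the resolved mate chromosome
#' name (`=` is expanded on read and re-compressed on write).
#' Coordinates are numeric (1-based; 0 for unavailable), so positions
#' beyond the 32-bit range are representable.
#'
#' @param qname,flag,rname,pos,mapq,cigar,rnext,pnext,tlen,seq,qual,tags
#'   vectors of equal length (scalars are recycled by data.table).
#' @return A data.table with the `SAM_COLS` layout.
#' @export
sam_records <- function(qname, flag, rname, pos, mapq, cigar,
                        rnext, pnext, tlen, seq, qual, tags = "") {
  data.table::data.table(
    qname = as.character(qname), flag = as.integer(flag),
    rname = as.character(rname), pos = as.numeric(pos),
    mapq = as.integer(mapq), cigar = as.character(cigar),
    rnext = as.character(rnext), pnext = as.numeric(pnext),
    tlen = as.numeric(tlen), seq = as.character(seq),
    qual = as.character(qual), tags = as.character(tags))
}

empty_records <- function() {
  sam_records(character(), integer(), character(), numeric(), integer(),
              character(), character(), numeric(), numeric(), character(),
              character(), character())
}

#' Build a SAM header for a genome index
#'
#' `@SQ` lines follow the genome index order (the global sort order).
#' The inter/intrachromosomal destination file is never given a fake
#' contig line: it is a file-naming convention, not a coordinate system.
#'
#' @param genome a [genome_index()], or `NULL` for a header with no
#'   `@SQ` lines.
#' @param sort_order `SO` value for the `@HD` line.
#' @return Character vector of header lines.
#' @export
sam_header <- function(genome = NULL, sort_order = "coordinate") {
  hd <- sprintf("@HD\tVN:1.6\tSO:%s", sort_order)
  if (is.null(genome)) return(hd)
  c(hd, sprintf("@SQ\tSN:%s\tLN:%s", genome$name, format_bp(genome$length)))
}

#' Read a SAM text file
#'
#' Plain-text SAM v1.6 only (no BAM/CRAM). The header is attached as
#' attribute `"header"`; `rnext` values of `=` are resolved to the
#' record's own `rname`.
#'
#' @param path SAM file path.
#' @return A records data.table (see [sam_records()]).
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  is_hdr <- startsWith(lines, "@")
  header <- lines[is_hdr]
  body <- lines[!is_hdr & nzchar(lines)]
  if (length(body) == 0L) {
    rec <- empty_records()
    data.table::setattr(rec, "header", header)
    return(rec)
  }
  parts <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 11L)) {
    bad <- which(nf < 11L)[1]
    stop(sprintf("malformed SAM record at line %d of %s",
                 which(!is_hdr & nzchar(lines))[bad], path), call. = FALSE)
  }
  fld <- function(i) vapply(parts, `[[`, "", i)
  tags <- vapply(parts, function(p) {
    if (length(p) > 11L) paste(p[-seq_len(11L)], collapse = "\t") else ""
  }, "")
  rec <- sam_records(fld(1), as.integer(fld(2)), fld(3), as.numeric(fld(4)),
                     as.integer(fld(5)), fld(6), fld(7), as.numeric(fld(8)),
                     as.numeric(fld(9)), fld(10), fld(11), tags)
  rec[rnext == "=", rnext := rname]
  data.table::setattr(rec, "header", header)
  rec[]
}

#' Write records as SAM text
#'
#' Output is byte-stable: field formatting is fixed, `rnext` equal to
#' `rname` is written as `=`, and no timestamps or tool lines are
#' emitted.
#'
#' @param records a records data.table.
#' @param path output path.
#' @param genome optional [genome_index()] used to build the header.
#' @param header explicit header lines (overrides `genome`).
#' @return `path`, invisibly.
#' @export
write_sam <- function(records, path, genome = NULL, header = NULL) {
  if (is.null(header)) header <- sam_header(genome)
  rn <- records$rnext
  rn[rn == records$rname & rn != "*"] <- "="
  body <- sprintf("%s\t%d\t%s\t%s\t%d\t%s\t%s\t%s\t%s\t%s\t%s",
                  records$qname, records$flag, records$rname,
                  format_bp(records$pos), records$mapq, records$cigar,
                  rn, format_bp(records$pnext), format_bp(records$tlen),
                  records$seq, records$qual)
  has_tags <- nzchar(records$tags)
  body[has_tags] <- paste(body[has_tags], records$tags[has_tags], sep = "\t")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(header, body), con)
  invisible(path)
}

#' Canonically sort records
#'
#' Sort key: chromosome (genome-index order, unmapped `*` last), then
#' `pos`, `qname`, `flag`. Every pipeline stage sorts its output this
#' way before writing, which is what erases scheduling nondeterminism.
#'
#' @param records records data.table.
#' @param genome optional [genome_index()] fixing chromosome order;
#'   without it chromosomes sort lexicographically.
#' @return Sorted copy of `records`.
#' @export
sort_records <- function(records, genome = NULL) {
  if (nrow(records) == 0L) return(data.table::copy(records))
  if (is.null(genome)) {
    lev <- sort(setdiff(unique(records$rname), "*"), method = "radix")
  } else {
    lev <- genome$name
  }
  r <- data.table::copy(records)
  r[, .chrord := match(rname, lev, nomatch = length(lev) + 1L)]
  # data.table radix sort: C-locale string collation, deterministic.
  # The key covers every field so ties cannot reorder distinct records.
  data.table::setorderv(r, c(".chrord", "pos", "qname", "flag", "mapq",
                             "cigar", "rnext", "pnext", "tlen", "seq",
                             "qual", "tags"))
  r[, .chrord := NULL]
  r[]
}
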