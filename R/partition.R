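#' Partition a genome into fixed-boundary subregions with overlap buffers
#'
#' Evenly subdivides a genome into approximately `M` subregions of fixed
#' boundaries, the unit of parallel work. The target subregion length is
#' `ceiling(total_genome_length / M)`; each chromosome is cut into
#' `ceiling(chrom_length / target_length)` consecutive pieces of the
#' target length, the final piece of each chromosome absorbing the
#' remainder. Subregions never span a chromosome boundary, so the
#' realized subregion count can exceed `M` by up to the number of
#' chromosomes minus one.
#'
#' Each subregion additionally carries a buffered calling window
#' extending `overlap` bp beyond each fixed boundary (clipped at the
#' chromosome ends). The buffers exist so that variants near or spanning
#' a fixed boundary are still seen in full by the calling stage; calls
#' landing in a buffer are later reconciled against the fixed boundaries
#' (see [reconcile_boundary_variants()]).
#'
#' All coordinates are 1-based inclusive.
#'
#' @param index a [genome_index()].
#' @param M requested number of subregions (positive integer).
#' @param overlap buffer size in bp added on each side of the fixed
#'   boundaries; default 3000.
#' @return An object of class `partition_plan`: a list with elements
#'   `genome` (the index), `subregions` (a data.table with columns
#'   `index` (0-based ordinal), `chrom`, `start`, `end`,
#'   `buffered_start`, `buffered_end`), `overlap` and `target_length`.
#' @examples
#' idx <- genome_index(c("chr1", "chr2"), c(100, 50))
#' partition_genome(idx, M = 3, overlap = 10)
#' @export
partition_genome <- function(index, M, overlap = 3000) {
  if (!inherits(index, "genome_index") || nrow(index) == 0L) {
    stop("'index' must be a non-empty genome_index", call. = FALSE)
  }
  if (!is.numeric(M) || length(M) != 1L || !is.finite(M) || M < 1 ||
      M != floor(M)) {
    stop("'M' must be a positive integer", call. = FALSE)
  }
  if (!is.numeric(overlap) || length(overlap) != 1L || overlap < 0) {
    stop("'overlap' must be a non-negative number", call. = FALSE)
  }
  total <- sum(index$length)
  target <- ceiling(total / M)
  pieces <- lapply(seq_len(nrow(index)), function(i) {
    len <- index$length[i]
    n <- ceiling(len / target)
    start <- (seq_len(n) - 1) * target + 1
    end <- pmin(start + target - 1, len)
    data.table::data.table(chrom = index$name[i], start = start, end = end,
                           chrom_length = len)
  })
  sub <- data.table::rbindlist(pieces)
  sub[, `:=`(index = seq_len(nrow(sub)) - 1L,
             buffered_start = pmax(1, start - overlap),
             buffered_end = pmin(chrom_length, end + overlap))]
  sub[, chrom_length := NULL]
  data.table::setcolorder(sub, c("index", "chrom", "start", "end",
                                 "buffered_start", "buffered_end"))
  structure(list(genome = index, subregions = sub[],
                 overlap = overlap, target_length = target),
            class = "partition_plan")
}

#' @export
print.partition_plan <- function(x, ...) {
  cat(sprintf(
    "<partition_plan> %d subregions, target length %s bp, overlap %s bp\n",
    nrow(x$subregions), format_bp(x$target_length), format_bp(x$overlap)))
  print(utils::head(x$subregions, 10))
  if (nrow(x$subregions) > 10) {
    cat(sprintf("... and %d more\n", nrow(x$subregions) - 10L))
  }
  invisible(x)
}

#' Locate the subregion owning a genomic position
#'
#' Maps positions to the subregion whose fixed boundaries
#' `[start, end]` contain them. The fixed intervals tile every
#' chromosome exactly, so the owner is unique.
#'
#' @param plan a [partition_genome()] plan.
#' @param chrom character vector of chromosome names.
#' @param pos numeric vector of 1-based positions (recycled against
#'   `chrom` in the usual way; lengths must match).
#' @return Integer vector of 0-based subregion ordinals; `NA` where the
#'   chromosome is unknown or the position lies outside it.
#' @export
locate_subregion <- function(plan, chrom, pos) {
  stopifnot(inherits(plan, "partition_plan"))
  if (length(chrom) != length(pos)) {
    stop("'chrom' and 'pos' must have equal length", call. = FALSE)
  }
  sub <- plan$subregions
  out <- rep(NA_integer_, length(chrom))
  for (cn in unique(chrom)) {
    rows <- which(sub$chrom == cn)
    sel <- which(chrom == cn)
    if (length(rows) == 0L) next
    starts <- sub$start[rows]
    k <- findInterval(pos[sel], starts)
    ok <- k >= 1L & pos[sel] <= sub$end[rows[pmax(k, 1L)]] & pos[sel] >= 1
    out[sel[ok]] <- sub$index[rows[k[ok]]]
  }
  out
}

#' Write a partition plan as GATK-style intervals text
#'
#' One line per subregion, `chrom:start-end`, 1-based inclusive over the
#' *buffered* calling window (the window actually handed to variant
#' calling). A `#overlap=<bp>` comment header records the buffer size so
#' the fixed boundaries can be reconstructed by [read_intervals()].
#'
#' @param plan a [partition_genome()] plan.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_intervals <- function(plan, path) {
  stopifnot(inherits(plan, "partition_plan"))
  sub <- plan$subregions
  lines <- c(sprintf("#overlap=%s", format_bp(plan$overlap)),
             sprintf("%s:%s-%s", sub$chrom, format_bp(sub$buffered_start),
                     format_bp(sub$buffered_end)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Read a GATK-style intervals file back into a partition plan
#'
#' Parses `chrom:start-end` lines (1-based inclusive), validates each
#' interval against the genome index, and reconstructs fixed subregion
#' boundaries from the buffered windows using the `#overlap=` header
#' (absent header means overlap 0, i.e. the lines are the fixed
#' boundaries). Reconstruction uses the tiling invariant: the first
#' fixed interval of a chromosome starts at 1 and the last ends at the
#' chromosome length; interior boundaries are recovered by stripping the
#' overlap from unclipped buffer edges.
#'
#' @param path intervals file path.
#' @param index the [genome_index()] the intervals refer to.
#' @return A `partition_plan`. Its `target_length` is set to the longest
#'   reconstructed fixed interval.
#' @export
read_intervals <- function(path, index) {
  stopifnot(inherits(index, "genome_index"))
  lines <- readLines(path)
  overlap <- 0
  hdr <- grep("^#overlap=", lines, value = TRUE)
  if (length(hdr)) overlap <- as.numeric(sub("^#overlap=", "", hdr[1]))
  keep <- which(nzchar(trimws(lines)) & !startsWith(trimws(lines), "#"))
  m <- regmatches(lines[keep],
                  regexec("^([^:]+):([0-9]+)-([0-9]+)$", trimws(lines[keep])))
  bad <- which(lengths(m) != 4L)
  if (length(bad)) {
    stop(sprintf("malformed interval at line %d of %s", keep[bad[1]], path),
         call. = FALSE)
  }
  dt <- data.table::data.table(
    line = keep,
    chrom = vapply(m, `[[`, "", 2L),
    bstart = as.numeric(vapply(m, `[[`, "", 3L)),
    bend = as.numeric(vapply(m, `[[`, "", 4L)))
  clen <- index$length[match(dt$chrom, index$name)]
  bad <- which(is.na(clen) | dt$bstart < 1 | dt$bend > clen |
                 dt$bstart > dt$bend)
  if (length(bad)) {
    stop(sprintf("interval at line %d outside genome index bounds: %s",
                 dt$line[bad[1]], lines[dt$line[bad[1]]]), call. = FALSE)
  }
  # reconstruct fixed boundaries chromosome by chromosome
  dt[, chrom_length := clen]
  pieces <- lapply(split(dt, factor(dt$chrom, levels = unique(dt$chrom))),
                   function(d) {
    d <- d[order(d$bstart), ]
    n <- nrow(d)
    start <- ifelse(d$bstart > 1, d$bstart + overlap, NA_real_)
    start[1] <- 1
    end <- ifelse(d$bend < d$chrom_length, d$bend - overlap, NA_real_)
    end[n] <- d$chrom_length[n]
    # cascade: a known end fixes the next start and vice versa
    for (i in seq_len(n)) {
      if (i > 1 && is.na(start[i]) && !is.na(end[i - 1])) {
        start[i] <- end[i - 1] + 1
      }
      if (i < n && is.na(end[i]) && !is.na(start[i + 1])) {
        end[i] <- start[i + 1] - 1
      }
    }
    for (i in rev(seq_len(n))) {
      if (i < n && is.na(end[i]) && !is.na(start[i + 1])) {
        end[i] <- start[i + 1] - 1
      }
      if (i > 1 && is.na(start[i]) && !is.na(end[i - 1])) {
        start[i] <- end[i - 1] + 1
      }
    }
    if (anyNA(start) || anyNA(end)) {
      stop("ambiguous intervals file: cannot reconstruct fixed boundaries",
           call. = FALSE)
    }
    if (any(start > end) || any(start[-1] != end[-n] + 1)) {
      stop("intervals do not tile chromosome ", d$chrom[1], call. = FALSE)
    }
    data.table::data.table(chrom = d$chrom, start = start, end = end,
                           buffered_start = d$bstart, buffered_end = d$bend)
  })
  sub <- data.table::rbindlist(pieces)
  # restore genome order
  sub <- sub[order(match(sub$chrom, index$name), sub$start)]
  sub[, index := seq_len(nrow(sub)) - 1L]
  data.table::setcolorder(sub, c("index", "chrom", "start", "end",
                                 "buffered_start", "buffered_end"))
  structure(list(genome = index, subregions = sub[], overlap = overlap,
                 target_length = max(sub$end - sub$start + 1)),
            class = "partition_plan")
}
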