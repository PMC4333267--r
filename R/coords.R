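#' CIGAR arithmetic
#'
#' Internal vectorized CIGAR helpers. All per-cigar quantities are
#' computed once per *unique* cigar string and mapped back, since real
#' alignment files contain few distinct cigars.
#'
#' @keywords internal
#' @name cigar-internal
NULL

cigar_split <- function(cigars) {
  m <- gregexpr("[0-9]+[MIDNSHP=X]", cigars)
  ops <- regmatches(cigars, m)
  lapply(ops, function(o) {
    if (length(o) == 1L && is.na(o[1])) {
      stop("invalid CIGAR string", call. = FALSE)
    }
    list(len = as.numeric(sub("[MIDNSHP=X]$", "", o)),
         op = sub("^[0-9]+", "", o))
  })
}

# per-unique-cigar summary: clip lengths, reference span, query length
cigar_stats <- function(cigars) {
  u <- unique(cigars)
  sp <- cigar_split(u)
  stats <- vapply(sp, function(s) {
    op <- s$op; len <- s$len
    n <- length(op)
    lead <- 0
    i <- 1L
    while (i <= n && op[i] %in% c("S", "H")) {
      lead <- lead + len[i]; i <- i + 1L
    }
    trail <- 0
    j <- n
    while (j >= 1L && op[j] %in% c("S", "H")) {
      trail <- trail + len[j]; j <- j - 1L
    }
    ref <- sum(len[op %in% c("M", "D", "N", "=", "X")])
    qlen <- sum(len[op %in% c("M", "I", "S", "=", "X")])
    c(lead, trail, ref, qlen)
  }, numeric(4))
  k <- match(cigars, u)
  list(leading_clip = stats[1, k], trailing_clip = stats[2, k],
       ref_span = stats[3, k], query_length = stats[4, k])
}

# For each unique cigar: reference offsets (0-based from pos) and query
# positions (1-based) of aligned (M/=/X) bases.
cigar_aligned_map <- function(u) {
  sp <- cigar_split(u)
  lapply(sp, function(s) {
    op <- s$op; len <- s$len
    roff <- numeric(0); qpos <- numeric(0)
    r <- 0; q <- 0
    for (i in seq_along(op)) {
      o <- op[i]; l <- len[i]
      if (o %in% c("M", "=", "X")) {
        roff <- c(roff, r + seq_len(l) - 1)
        qpos <- c(qpos, q + seq_len(l))
        r <- r + l; q <- q + l
      } else if (o %in% c("D", "N")) {
        r <- r + l
      } else if (o %in% c("I", "S")) {
        q <- q + l
      } # H, P consume nothing
    }
    list(roff = roff, qpos = qpos)
  })
}

# For each unique cigar: indel events with the reference offset of the
# anchor base (the aligned base immediately left of the event) and, for
# insertions, the query range of the inserted bases.
cigar_indel_events <- function(u) {
  sp <- cigar_split(u)
  lapply(sp, function(s) {
    op <- s$op; len <- s$len
    ev <- list()
    r <- 0; q <- 0
    for (i in seq_along(op)) {
      o <- op[i]; l <- len[i]
      if (o %in% c("M", "=", "X")) {
        r <- r + l; q <- q + l
      } else if (o %in% c("D", "N")) {
        if (o == "D" && r > 0) {
          ev[[length(ev) + 1L]] <- list(type = "D", anchor_off = r - 1,
                                        len = l, qstart = NA_real_)
        }
        r <- r + l
      } else if (o == "I") {
        if (r > 0) {
          ev[[length(ev) + 1L]] <- list(type = "I", anchor_off = r - 1,
                                        len = l, qstart = q + 1)
        }
        q <- q + l
      } else if (o == "S") {
        q <- q + l
      }
    }
    ev
  })
}

#' Unclipped 5' coordinates of mapped reads
#'
#' The "external coordinates" used for duplicate marking: for a
#' forward-strand read, the leftmost aligned position minus any leading
#' soft/hard clip; for a reverse-strand read, the reference end of the
#' alignment plus any trailing soft/hard clip. Two reads from the same
#' original molecule share this coordinate even when their clipping
#' differs.
#'
#' @param records records data.table; all rows must be mapped with a
#'   valid CIGAR.
#' @return A data.table with columns `chrom`, `pos5` and `strand`
#'   (`"+"`/`"-"`), one row per input record.
#' @examples
#' r <- sam_records("q", 0L, "chr1", 100, 60L, "5S95M", "*", 0, 0,
#'                  strrep("A", 100), strrep("I", 100))
#' unclipped_five_prime(r)  # pos5 = 95
#' @export
unclipped_five_prime <- function(records) {
  if (nrow(records) == 0L) {
    return(data.table::data.table(chrom = character(), pos5 = numeric(),
                                  strand = character()))
  }
  if (any(is_unmapped(records$flag)) || any(records$cigar == "*")) {
    stop("unclipped_five_prime is undefined for unmapped reads",
         call. = FALSE)
  }
  st <- cigar_stats(records$cigar)
  rev <- is_reverse(records$flag)
  pos5 <- ifelse(rev,
                 records$pos + st$ref_span - 1 + st$trailing_clip,
                 records$pos - st$leading_clip)
  data.table::data.table(chrom = records$rname, pos5 = pos5,
                         strand = ifelse(rev, "-", "+"))
}

#' Duplicate keys for primary records
#'
#' Computes, per template (qname), the external-coordinate key under
#' which PCR/optical duplicates collide: the canonical (lexicographically
#' ordered) pair of `chrom:unclipped5':strand` triples of the two
#' primary mates, plus a library tag. Templates with one unmapped mate
#' get a single-end key (mapped triple plus a `*` sentinel); the
#' sentinel keeps single-end keys disjoint from pair keys. Templates
#' with no mapped primary record, and lone primary records whose mate is
#' mapped elsewhere (e.g. reads redistributed from the
#' inter/intrachromosomal file after its own deduplication), get `NA`:
#' they are exempt from duplicate grouping.
#'
#' Secondary and supplementary records never contribute to keys.
#'
#' @param records records data.table.
#' @param library library tag appended to every key; default a single
#'   library, matching samples without read-group annotation.
#' @return A data.table with one row per distinct qname among primary
#'   records: `qname`, `key` (character or `NA`), `mapq_sum` (sum of
#'   primary mates' MAPQ) and `baseq_sum` (sum of base qualities >= 15,
#'   the Picard-style alternative survivor score).
#' @export
duplicate_keys <- function(records, library = "lib") {
  prim <- records[is_primary(records$flag)]
  if (nrow(prim) == 0L) {
    # note: `key` must be added via := because data.table() reserves
    # the argument name for its sort key
    empty <- data.table::data.table(qname = character(),
                                    mapq_sum = numeric(),
                                    baseq_sum = numeric())
    empty[, key := character()]
    data.table::setcolorder(empty, c("qname", "key", "mapq_sum",
                                     "baseq_sum"))
    return(empty[])
  }
  mapped <- !is_unmapped(prim$flag)
  triple <- rep(NA_character_, nrow(prim))
  if (any(mapped)) {
    u5 <- unclipped_five_prime(prim[mapped])
    triple[mapped] <- sprintf("%s:%s:%s", u5$chrom, format_bp(u5$pos5),
                              u5$strand)
  }
  bq <- baseq_score(prim$qual)
  dt <- data.table::data.table(qname = prim$qname, triple = triple,
                               mapped = mapped,
                               paired = bitwAnd(prim$flag, FLAG_PAIRED) != 0L,
                               mate_unmapped = is_mate_unmapped(prim$flag),
                               mapq = ifelse(mapped, prim$mapq, 0L),
                               bq = bq)
  tot <- dt[, list(n = .N, mapq_sum = sum(mapq), baseq_sum = sum(bq)),
            by = "qname"]
  mp <- dt[mapped == TRUE]
  if (nrow(mp)) {
    data.table::setorder(mp, qname, triple)  # canonical mate order
    mk <- mp[, list(nm = .N, t1 = triple[1L], t2 = triple[.N],
                    se_mate_unmapped = mate_unmapped[1L],
                    se_unpaired = !paired[1L]), by = "qname"]
  } else {
    mk <- data.table::data.table(qname = character(), nm = integer(),
                                 t1 = character(), t2 = character(),
                                 se_mate_unmapped = logical(),
                                 se_unpaired = logical())
  }
  out <- merge(tot, mk, by = "qname", all.x = TRUE, sort = TRUE)
  out[, nm := data.table::fifelse(is.na(nm), 0L, nm)]
  # single-end key only when the mate is genuinely unmapped (present in
  # the group, flagged mate-unmapped, or the read is unpaired); a lone
  # mate of a mapped pair is dedup-exempt (key NA)
  se_ok <- out$nm == 1L &
    (out$n == 2L | out$se_mate_unmapped | out$se_unpaired)
  out[, key := NA_character_]
  out[nm == 2L, key := paste(t1, t2, library, sep = "|")]
  out[se_ok, key := paste(t1, "*", library, sep = "|")]
  out[, list(qname, key, mapq_sum, baseq_sum)]
}

# Picard-style base-quality score: sum of qualities >= 15 across SEQ
baseq_score <- function(qual) {
  vapply(qual, function(q) {
    if (identical(q, "*") || !nzchar(q)) return(0)
    v <- utf8ToInt(q) - 33L
    sum(v[v >= 15L])
  }, numeric(1), USE.NAMES = FALSE)
}
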