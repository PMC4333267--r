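# ---- per-base expansion helpers (shared by recalibration and calling) ----

# base codes: A=0 C=1 G=2 T=3, anything else (incl. N) = 4
BASE_CODE <- local({
  v <- rep(4L, 256)
  v[utf8ToInt("A") + 1L] <- 0L
  v[utf8ToInt("C") + 1L] <- 1L
  v[utf8ToInt("G") + 1L] <- 2L
  v[utf8ToInt("T") + 1L] <- 3L
  v
})
BASE_LETTER <- c("A", "C", "G", "T", "N")

# dinucleotide context ids: prev*4 + cur for ACGT pairs (0..15),
# 16 = sentinel (read start, or preceding base not ACGT); the label of
# id prev*4+cur is paste0(prev, cur)
CTX_SENTINEL <- 16L
CTX_LEVELS <- c(paste0(rep(BASE_LETTER[1:4], each = 4),
                       rep(BASE_LETTER[1:4], times = 4)), "--")

base_codes_of <- function(raw_vec) BASE_CODE[as.integer(raw_vec) + 1L]

# concatenate strings into one raw vector + 0-based offsets
concat_raw <- function(strings) {
  list(raw = charToRaw(paste(strings, collapse = "")),
       off = c(0, cumsum(nchar(strings))))
}

# Expand mapped records into one row per aligned (M/=/X) base:
# columns row (record index), refpos, qpos.
expand_aligned <- function(records) {
  if (nrow(records) == 0L) {
    return(data.table::data.table(row = integer(), refpos = numeric(),
                                  qpos = numeric()))
  }
  u <- unique(records$cigar)
  maps <- cigar_aligned_map(u)
  k <- match(records$cigar, u)
  nb <- vapply(maps, function(m) length(m$roff), numeric(1))[k]
  row <- rep(seq_len(nrow(records)), nb)
  mk <- maps[k]
  roff <- unlist(lapply(mk, `[[`, "roff"), use.names = FALSE)
  qpos <- unlist(lapply(mk, `[[`, "qpos"), use.names = FALSE)
  data.table::data.table(row = row, refpos = records$pos[row] + roff,
                         qpos = qpos)
}

# reference base codes for (chrom, refpos) pairs; ref_raw is a named
# list of charToRaw(chromosome sequence)
ref_codes_at <- function(ref_raw, chrom, refpos) {
  out <- integer(length(chrom))
  for (cn in unique(chrom)) {
    sel <- chrom == cn
    r <- ref_raw[[cn]]
    if (is.null(r)) {
      stop("reference sequence missing for chromosome ", cn, call. = FALSE)
    }
    if (any(refpos[sel] > length(r))) {
      stop("integrity error: alignment span exceeds reference length on ",
           cn, call. = FALSE)
    }
    out[sel] <- base_codes_of(r[refpos[sel]])
  }
  out
}

reference_raw <- function(reference) lapply(reference, charToRaw)

# ---- covariate model ----

#' Build a base-quality covariate table
#'
#' Counts observed bases and reference mismatches binned by the three
#' covariates of the recalibration model: reported quality score,
#' machine cycle (1-based position within the read as stored, negated
#' for second-of-pair mates) and dinucleotide context (preceding +
#' current read base; a sentinel bin `--` at the read start or when the
#' preceding base is not A/C/G/T).
#'
#' Only aligned (`M`/`=`/`X`) bases of mapped primary records are
#' counted; insertions and clipped bases consume no reference and are
#' skipped, as are positions where the read base or the reference base
#' is `N`.
#'
#' @param records records data.table (typically deduplicated).
#' @param reference named character vector of chromosome sequences.
#' @return A `covariate_table`: data.table with columns `reported_q`,
#'   `cycle`, `context`, `observations`, `mismatches`, sorted so equal
#'   tables serialize to identical bytes.
#' @export
build_covariate_table <- function(records, reference) {
  rec <- records[is_primary(records$flag) & !is_unmapped(records$flag) &
                   records$seq != "*" & records$qual != "*"]
  if (nrow(rec) == 0L) return(empty_covariate_table())
  ex <- expand_aligned(rec)
  sq <- concat_raw(rec$seq)
  qu <- concat_raw(rec$qual)
  gidx <- sq$off[ex$row] + ex$qpos
  cur <- base_codes_of(sq$raw[gidx])
  q <- as.integer(qu$raw[gidx]) - 33L
  prev <- rep(CTX_SENTINEL, nrow(ex))
  inner <- ex$qpos > 1
  prev[inner] <- base_codes_of(sq$raw[gidx[inner] - 1L])
  ctx <- ifelse(ex$qpos == 1L | prev >= 4L, CTX_SENTINEL,
                prev * 4L + cur)
  ctx[cur >= 4L] <- CTX_SENTINEL  # value irrelevant, rows dropped below
  cyc <- as.integer(ex$qpos)
  second <- is_second_of_pair(rec$flag)[ex$row]
  cyc[second] <- -cyc[second]
  refc <- ref_codes_at(reference_raw(reference), rec$rname[ex$row],
                       ex$refpos)
  keep <- cur < 4L & refc < 4L
  dt <- data.table::data.table(reported_q = q[keep], cycle = cyc[keep],
                               ctx = ctx[keep],
                               mm = as.integer(cur[keep] != refc[keep]))
  tab <- dt[, list(observations = as.numeric(.N),
                   mismatches = as.numeric(sum(mm))),
            by = c("reported_q", "cycle", "ctx")]
  tab[, context := CTX_LEVELS[ctx + 1L]]
  tab[, ctx := NULL]
  finalize_covariate_table(tab)
}

empty_covariate_table <- function() {
  finalize_covariate_table(data.table::data.table(
    reported_q = integer(), cycle = integer(), context = character(),
    observations = numeric(), mismatches = numeric()))
}

finalize_covariate_table <- function(tab) {
  data.table::setcolorder(tab, c("reported_q", "cycle", "context",
                                 "observations", "mismatches"))
  data.table::setorderv(tab, c("reported_q", "cycle", "context"))
  data.table::setattr(tab, "class",
                      c("covariate_table", class(data.table::data.table())))
  tab[]
}

#' Merge covariate tables by bin-wise addition
#'
#' The merge is field-wise addition over bins, hence associative and
#' commutative with the empty table as identity: the merge of
#' per-subregion tables equals, bin-exactly, the table built on all
#' records at once. This is what lets each parallel recalibration
#' instance see genome-wide counts.
#'
#' @param tables list of `covariate_table`s.
#' @return A single merged `covariate_table`.
#' @export
merge_covariate_tables <- function(tables) {
  if (length(tables) == 0L) return(empty_covariate_table())
  all <- data.table::rbindlist(tables)
  tab <- all[, list(observations = sum(observations),
                    mismatches = sum(mismatches)),
             by = c("reported_q", "cycle", "context")]
  finalize_covariate_table(tab)
}

#' Empirical Phred quality of a covariate bin
#'
#' `Q = round(-10 * log10((mismatches + 1) / (observations + 2)))`,
#' clamped to `[2, 60]`. The +1/+2 pseudocounts keep empty and
#' mismatch-free bins finite (an empty bin maps to Q3); the floor and
#' cap avoid Phred 0/1 pathologies and unbounded scores on huge clean
#' bins.
#'
#' @param observations,mismatches numeric vectors of bin counts.
#' @return Integer vector of recalibrated Phred scores.
#' @examples
#' empirical_quality(9998, 0)  # 40
#' empirical_quality(0, 0)     # 3
#' @export
empirical_quality <- function(observations, mismatches) {
  q <- round(-10 * log10((mismatches + 1) / (observations + 2)))
  as.integer(pmin(60, pmax(2, q)))
}

#' Apply recalibration to read qualities
#'
#' Replaces every base quality by the empirical quality of the base's
#' covariate bin in the (genome-wide, merged) table; bases whose bin is
#' absent from the table keep their reported quality. All query bases
#' are recalibrated, including soft-clipped ones, so the transform
#' depends only on the read itself and the global table — never on
#' which subregion the read sits in. No downsampling is performed.
#'
#' @param records records data.table.
#' @param table merged `covariate_table`.
#' @return A copy of `records` with recalibrated `qual` strings.
#' @export
apply_recalibration <- function(records, table) {
  out <- data.table::copy(records)
  idx <- which(out$seq != "*" & out$qual != "*" &
                 nchar(out$seq) == nchar(out$qual))
  if (length(idx) == 0L) return(out)
  rec <- out[idx]
  nb <- nchar(rec$seq)
  row <- rep(seq_along(idx), nb)
  qpos <- sequence(nb)
  sq <- concat_raw(rec$seq)
  qu <- concat_raw(rec$qual)
  gidx <- sq$off[row] + qpos
  cur <- base_codes_of(sq$raw[gidx])
  q <- as.integer(qu$raw[gidx]) - 33L
  prev <- rep(CTX_SENTINEL, length(gidx))
  inner <- qpos > 1
  prev[inner] <- base_codes_of(sq$raw[gidx[inner] - 1L])
  ctx <- ifelse(qpos == 1L | prev >= 4L | cur >= 4L, CTX_SENTINEL,
                prev * 4L + cur)
  cyc <- as.integer(qpos)
  second <- is_second_of_pair(rec$flag)[row]
  cyc[second] <- -cyc[second]
  look <- data.table::data.table(reported_q = q, cycle = cyc,
                                 context = CTX_LEVELS[ctx + 1L])
  tb <- data.table::as.data.table(table)
  hit <- tb[look, on = c("reported_q", "cycle", "context"),
            list(observations, mismatches)]
  newq <- q
  got <- !is.na(hit$observations)
  newq[got] <- empirical_quality(hit$observations[got],
                                 hit$mismatches[got])
  big <- intToUtf8(newq + 33L)
  starts <- qu$off[seq_along(nb)] + 1L
  out[idx, qual := substring(big, starts, starts + nb - 1L)]
  out
}

#' Serialize a covariate table as sorted TSV
#'
#' @param table a `covariate_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_covariate_table <- function(table, path) {
  tab <- finalize_covariate_table(data.table::copy(
    data.table::as.data.table(table)))
  data.table::fwrite(tab, path, sep = "\t", quote = FALSE,
                     scipen = 999L)
  invisible(path)
}

#' Read a covariate table TSV
#'
#' @param path TSV path written by [write_covariate_table()].
#' @return A `covariate_table`.
#' @export
read_covariate_table <- function(path) {
  tab <- data.table::fread(path, sep = "\t",
                           colClasses = list(
                             integer = c("reported_q", "cycle"),
                             character = "context",
                             numeric = c("observations", "mismatches")))
  finalize_covariate_table(tab)
}
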