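#' Plumbing pileup variant caller over a buffered subregion window
#'
#' A deliberately simple, fully specified position-wise caller used to
#' exercise the parallelization invariants without an external
#' genotyper; it is pluggable behind the pipeline's calling stage for
#' users who shell out to production callers.
#'
#' For every reference position of the buffered window, primary-read
#' aligned (`M`/`=`/`X`) bases are counted. A SNP is emitted when the
#' most frequent non-reference base (ties broken by base order
#' A<C<G<T) reaches `min_alt_frac` of the position depth and the depth
#' is at least `min_depth`; the genotype is hom when the fraction
#' reaches `hom_frac`, else het. Indels are called from CIGAR `I`/`D`
#' evidence, leftmost-anchored at the aligned base preceding the
#' event, under the same thresholds against the anchor-position depth.
#' `N` bases (read or reference) are excluded.
#'
#' The QUAL score is a deterministic binomial-tail mis-call proxy:
#' `-10*log10 P[X >= alt_count]` with
#' `X ~ Binomial(depth, error_rate)`, rounded to one decimal.
#'
#' @param window one subregion: a one-row subset of
#'   `plan$subregions` (or any list with `chrom`, `buffered_start`,
#'   `buffered_end`, `index`).
#' @param records evidence records: the subregion's deduplicated,
#'   recalibrated reads plus adjacent-subregion reads overlapping the
#'   buffered window (see [gather_window_records()]).
#' @param reference named character vector of chromosome sequences.
#' @param min_depth minimum position depth; default 8.
#' @param min_alt_frac minimum alternate-allele fraction; default 0.2.
#' @param hom_frac fraction at or above which the genotype is hom;
#'   default 0.8.
#' @param error_rate assumed per-base mis-call rate of the QUAL proxy;
#'   default 0.01.
#' @return A data.table of calls: `chrom`, `pos`, `ref`, `alt`,
#'   `qual`, `genotype` (`"het"`/`"hom"`), `depth`,
#'   `subregion_index` (provenance), sorted by `(pos, ref, alt)`.
#' @export
pileup_call <- function(window, records, reference, min_depth = 8L,
                        min_alt_frac = 0.2, hom_frac = 0.8,
                        error_rate = 0.01) {
  chrom <- window$chrom
  bstart <- window$buffered_start
  bend <- window$buffered_end
  if (is.null(reference[[chrom]]) ||
      bend > nchar(reference[[chrom]]) || bstart < 1) {
    stop("window outside reference: ", chrom, call. = FALSE)
  }
  empty <- data.table::data.table(
    chrom = character(), pos = numeric(), ref = character(),
    alt = character(), qual = numeric(), genotype = character(),
    depth = numeric(), subregion_index = integer())
  rec <- records[is_primary(records$flag) & !is_unmapped(records$flag) &
                   records$rname == chrom & records$seq != "*"]
  if (nrow(rec) == 0L) return(empty)
  st <- cigar_stats(rec$cigar)
  rec <- rec[rec$pos <= bend & rec$pos + st$ref_span - 1 >= bstart]
  if (nrow(rec) == 0L) return(empty)
  refraw <- charToRaw(reference[[chrom]])
  refcode <- base_codes_of(refraw)

  ex <- expand_aligned(rec)
  sq <- concat_raw(rec$seq)
  cur <- base_codes_of(sq$raw[sq$off[ex$row] + ex$qpos])
  inwin <- ex$refpos >= bstart & ex$refpos <= bend & cur < 4L
  piles <- data.table::data.table(refpos = ex$refpos[inwin],
                                  code = cur[inwin])
  if (nrow(piles) == 0L) return(empty)
  depth_tab <- piles[, list(depth = as.numeric(.N)), by = "refpos"]

  # SNPs
  piles[, refc := refcode[refpos]]
  altcnt <- piles[code != refc & refc < 4L,
                  list(count = as.numeric(.N)), by = c("refpos", "code")]
  snps <- empty
  if (nrow(altcnt)) {
    data.table::setorderv(altcnt, c("refpos", "count", "code"),
                          order = c(1L, -1L, 1L))
    top <- altcnt[!duplicated(altcnt$refpos)]
    top <- merge(top, depth_tab, by = "refpos")
    top <- top[top$depth >= min_depth &
                 top$count / top$depth >= min_alt_frac, ]
    if (nrow(top)) {
      snps <- data.table::data.table(
        chrom = chrom, pos = top$refpos,
        ref = BASE_LETTER[refcode[top$refpos] + 1L],
        alt = BASE_LETTER[top$code + 1L],
        qual = call_qual(top$count, top$depth, error_rate),
        genotype = ifelse(top$count / top$depth >= hom_frac, "hom", "het"),
        depth = top$depth, subregion_index = as.integer(window$index))
    }
  }

  # indels from CIGAR evidence, anchored at the aligned base to the left
  indels <- empty
  u <- unique(rec$cigar)
  evs <- cigar_indel_events(u)
  if (any(lengths(evs) > 0)) {
    k <- match(rec$cigar, u)
    rows <- list()
    for (i in which(lengths(evs)[k] > 0L)) {
      for (e in evs[[k[i]]]) {
        anchor <- rec$pos[i] + e$anchor_off
        if (anchor < bstart || anchor > bend) next
        ins <- if (e$type == "I") {
          substr(rec$seq[i], e$qstart, e$qstart + e$len - 1)
        } else ""
        rows[[length(rows) + 1L]] <- data.table::data.table(
          anchor = anchor, type = e$type, len = e$len, ins = ins)
      }
    }
    if (length(rows)) {
      ev <- data.table::rbindlist(rows)
      sup <- ev[, list(support = as.numeric(.N)),
                by = c("anchor", "type", "len", "ins")]
      sup <- merge(sup, depth_tab, by.x = "anchor", by.y = "refpos",
                   all.x = TRUE)
      sup[is.na(depth), depth := support]
      sup <- sup[sup$depth >= min_depth &
                   sup$support / sup$depth >= min_alt_frac, ]
      if (nrow(sup)) {
        refstr <- reference[[chrom]]
        anchor_base <- substring(refstr, sup$anchor, sup$anchor)
        ref_al <- ifelse(sup$type == "D",
                         substring(refstr, sup$anchor,
                                   sup$anchor + sup$len),
                         anchor_base)
        alt_al <- ifelse(sup$type == "D", anchor_base,
                         paste0(anchor_base, sup$ins))
        indels <- data.table::data.table(
          chrom = chrom, pos = sup$anchor, ref = ref_al, alt = alt_al,
          qual = call_qual(sup$support, sup$depth, error_rate),
          genotype = ifelse(sup$support / sup$depth >= hom_frac,
                            "hom", "het"),
          depth = sup$depth, subregion_index = as.integer(window$index))
      }
    }
  }
  out <- data.table::rbindlist(list(snps, indels))
  out <- out[out$ref != out$alt, ]
  data.table::setorderv(out, c("pos", "ref", "alt"))
  out[]
}

# deterministic binomial-tail QUAL proxy, one decimal, capped at 9999
call_qual <- function(alt_count, depth, error_rate) {
  lp <- stats::pbinom(alt_count - 1, depth, error_rate,
                      lower.tail = FALSE, log.p = TRUE)
  q <- -10 * lp / log(10)
  round(pmin(q, 9999), 1)
}

#' Gather calling evidence for one buffered window
#'
#' Collects the subregion's own reads plus reads of the adjacent
#' subregions (same chromosome) whose alignment spans overlap the
#' buffered window. `per_subregion` is a list of record tables indexed
#' by subregion ordinal + 1.
#'
#' @param per_subregion list of records data.tables, one per subregion.
#' @param plan a [partition_genome()] plan.
#' @param k 0-based subregion ordinal.
#' @return Records data.table of the window's evidence.
#' @export
gather_window_records <- function(per_subregion, plan, k) {
  sub <- plan$subregions
  w <- sub[sub$index == k, ]
  neigh <- sub$index[sub$chrom == w$chrom &
                       abs(sub$index - k) <= 1L]
  recs <- data.table::rbindlist(per_subregion[neigh + 1L])
  if (nrow(recs) == 0L) return(recs)
  st <- cigar_stats(recs$cigar)
  recs[recs$rname == w$chrom & recs$pos <= w$buffered_end &
         recs$pos + st$ref_span - 1 >= w$buffered_start]
}

#' Assign variant calls to their owning subregion
#'
#' Ownership is decided solely from the call's anchor position (POS)
#' relative to the fixed subregion boundaries; the fixed intervals tile
#' each chromosome, so the owner is unique. A boundary position itself
#' belongs to the subregion whose inclusive `[start, end]` contains it
#' (the left neighbour of a boundary at `end`).
#'
#' @param calls calls data.table (columns `chrom`, `pos`).
#' @param plan a [partition_genome()] plan.
#' @return Integer vector of owning 0-based subregion ordinals.
#' @export
assign_subregion <- function(calls, plan) {
  locate_subregion(plan, calls$chrom, calls$pos)
}

#' Reconcile buffer-zone variant calls
#'
#' A variant inside an overlap buffer is called twice: once by its
#' owning subregion and once by the neighbour whose buffer covers it.
#' Reconciliation keeps a call iff its provenance subregion equals its
#' owner under [assign_subregion()] — the owner's record verbatim —
#' and discards the buffer-zone duplicate. The merged list is sorted
#' by (chromosome order, pos, ref, alt). Distinct alleles at one site
#' are distinct variants and are all kept.
#'
#' @param calls combined per-subregion calls (with
#'   `subregion_index` provenance).
#' @param plan a [partition_genome()] plan.
#' @return Reconciled, sorted calls; `(chrom, pos, ref, alt)` is unique.
#' @export
reconcile_boundary_variants <- function(calls, plan) {
  if (nrow(calls) == 0L) return(data.table::copy(calls))
  owner <- assign_subregion(calls, plan)
  kept <- calls[!is.na(owner) & owner == calls$subregion_index]
  kept <- data.table::copy(kept)
  kept[, .chrord := match(chrom, plan$genome$name)]
  data.table::setorderv(kept, c(".chrord", "pos", "ref", "alt"))
  kept[, .chrord := NULL]
  dup <- duplicated(kept[, c("chrom", "pos", "ref", "alt")])
  if (any(dup)) {
    stop("integrity error: duplicated variant after reconciliation at ",
         kept$chrom[dup][1], ":", format_bp(kept$pos[dup][1]),
         call. = FALSE)
  }
  kept[]
}

#' Write calls as a minimal VCF 4.2 file
#'
#' Fixed header (no timestamps; contig lines in genome-index order), so
#' equal call sets serialize to identical bytes. Columns: CHROM, POS,
#' ID (`.`), REF, ALT, QUAL, FILTER (`.`), INFO (`DP=`), FORMAT (`GT`)
#' and one sample (`0/1` het, `1/1` hom).
#'
#' @param calls calls data.table, sorted by (chromosome order, pos,
#'   ref, alt).
#' @param genome a [genome_index()].
#' @param path output path.
#' @param sample sample column name.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(calls, genome, path, sample = "sample") {
  ord <- order(match(calls$chrom, genome$name), calls$pos,
               calls$ref, calls$alt, method = "radix")
  if (!identical(ord, seq_len(nrow(calls)))) {
    stop("contract violation: calls must be sorted before writing",
         call. = FALSE)
  }
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%s>", genome$name,
            format_bp(genome$length)),
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample, sep = "\t"))
  body <- character(0)
  if (nrow(calls)) {
    qual <- ifelse(is.na(calls$qual), ".",
                   sprintf("%.1f", calls$qual))
    info <- ifelse(is.na(calls$depth), ".",
                   sprintf("DP=%s", format_bp(calls$depth)))
    gt <- ifelse(calls$genotype == "hom", "1/1", "0/1")
    body <- sprintf("%s\t%s\t.\t%s\t%s\t%s\t.\t%s\tGT\t%s",
                    calls$chrom, format_bp(calls$pos), calls$ref,
                    calls$alt, qual, info, gt)
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(header, body), con)
  invisible(path)
}

#' Read a VCF written by this package
#'
#' Minimal single-sample parser for the dialect of [write_vcf()]
#' (used for truth comparison and round-trip tests).
#'
#' @param path VCF path.
#' @return Calls data.table with `chrom`, `pos`, `ref`, `alt`, `qual`,
#'   `genotype`, `depth`.
#' @export
read_vcf <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  if (length(body) == 0L) {
    return(data.table::data.table(
      chrom = character(), pos = numeric(), ref = character(),
      alt = character(), qual = numeric(), genotype = character(),
      depth = numeric()))
  }
  p <- data.table::tstrsplit(body, "\t", fixed = TRUE)
  gt <- vapply(strsplit(p[[10]], ":", fixed = TRUE), `[[`, "", 1L)
  dp <- rep(NA_real_, length(body))
  m <- regmatches(p[[8]], regexec("DP=([0-9]+)", p[[8]]))
  has <- lengths(m) == 2L
  dp[has] <- as.numeric(vapply(m[has], `[[`, "", 2L))
  data.table::data.table(
    chrom = p[[1]], pos = as.numeric(p[[2]]), ref = p[[4]], alt = p[[5]],
    qual = suppressWarnings(as.numeric(p[[6]])),
    genotype = ifelse(gt == "1/1", "hom", "het"), depth = dp)
}

#' Concatenate per-subregion VCF fragments
#'
#' Fragments must share one header (same genome, same sample) and be
#' ordered by subregion; their record lines are concatenated under the
#' first fragment's header. For reconciled fragments this equals
#' [write_vcf()] of the merged call list.
#'
#' @param paths ordered VCF fragment paths.
#' @param out output path.
#' @return `out`, invisibly.
#' @export
concat_vcf <- function(paths, out) {
  stopifnot(length(paths) >= 1L)
  first <- readLines(paths[1])
  header <- first[startsWith(first, "#")]
  bodies <- lapply(paths, function(p) {
    lines <- readLines(p)
    h <- lines[startsWith(lines, "#")]
    if (!identical(h, header)) {
      stop("VCF fragments have differing headers: ", p, call. = FALSE)
    }
    lines[!startsWith(lines, "#")]
  })
  con <- file(out, "w")
  on.exit(close(con))
  writeLines(c(header, unlist(bodies)), con)
  invisible(out)
}
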