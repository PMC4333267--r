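#' Subregion routing of read pairs
#'
#' A template's routing destination is decided from the unclipped 5'
#' positions of its two primary mates — the same coordinates that make
#' up its duplicate key. If both mates' 5' positions fall inside the
#' fixed boundaries of the same subregion, the pair belongs to that
#' subregion; otherwise (mates in different subregions of one
#' chromosome, or on different chromosomes) the pair is diverted to the
#' inter/intrachromosomal destination `chrI`. Pairs with one unmapped
#' mate route by the mapped mate; fully unmapped templates go to `chrI`
#' (they have no coordinates anywhere else).
#'
#' Because duplicates share unclipped 5' coordinates exactly, any two
#' templates with equal duplicate keys receive the same destination —
#' the closure property that makes per-destination deduplication
#' exactly equivalent to genome-wide deduplication.
#'
#' Secondary and supplementary records follow their template's primary
#' pair. A lone secondary/supplementary record without a primary in the
#' input routes by its own coordinate.
#'
#' @param records records data.table.
#' @param plan a [partition_genome()] plan.
#' @return Integer vector, one entry per record: the 0-based subregion
#'   ordinal, or `-1L` for the `chrI` destination.
#' @export
route_records <- function(records, plan) {
  if (nrow(records) == 0L) return(integer(0))
  prim <- records[is_primary(records$flag)]
  pm <- prim[!is_unmapped(prim$flag)]
  if (nrow(pm)) {
    u5 <- unclipped_five_prime(pm)
    sub <- locate_subregion(plan, u5$chrom, u5$pos5)
    if (anyNA(sub)) {
      i <- which(is.na(sub))[1]
      stop(sprintf(
        "routing error: read %s maps at %s:%s, outside every subregion",
        pm$qname[i], u5$chrom[i], format_bp(u5$pos5[i])), call. = FALSE)
    }
    per <- data.table::data.table(qname = pm$qname, sub = sub)
    per <- per[, list(nm = .N, s1 = min(sub), s2 = max(sub)), by = "qname"]
  } else {
    per <- data.table::data.table(qname = character(), nm = integer(),
                                  s1 = integer(), s2 = integer())
  }
  # all primary qnames, including fully-unmapped templates
  allq <- unique(prim$qname)
  dest_by_q <- data.table::data.table(qname = allq)
  dest_by_q <- merge(dest_by_q, per, by = "qname", all.x = TRUE)
  dest_by_q[, dest := data.table::fifelse(
    is.na(nm), -1L,                       # no mapped primary -> chrI
    data.table::fifelse(s1 == s2, as.integer(s1), -1L))]
  dest <- dest_by_q$dest[match(records$qname, dest_by_q$qname)]
  # records whose qname has no primary at all: route by own coordinate
  orphan <- which(is.na(dest))
  if (length(orphan)) {
    om <- orphan[!is_unmapped(records$flag[orphan])]
    if (length(om)) {
      u5 <- unclipped_five_prime(records[om])
      s <- locate_subregion(plan, u5$chrom, u5$pos5)
      dest[om] <- data.table::fifelse(is.na(s), -1L, s)
    }
    dest[is.na(dest)] <- -1L
  }
  as.integer(dest)
}

#' Routing destination of a single read pair
#'
#' Convenience wrapper around [route_records()] for one template.
#'
#' @param pair records data.table holding one template's records.
#' @param plan a [partition_genome()] plan.
#' @return A list with `kind` (`"SUBREGION"` or `"CHR_I"`) and
#'   `subregion_index` (0-based ordinal, `NA` for `chrI`).
#' @export
route_pair <- function(pair, plan) {
  if (length(unique(pair$qname)) != 1L) {
    stop("'pair' must hold records of a single template", call. = FALSE)
  }
  d <- unique(route_records(pair, plan))
  stopifnot(length(d) == 1L)
  if (d < 0L) {
    list(kind = "CHR_I", subregion_index = NA_integer_)
  } else {
    list(kind = "SUBREGION", subregion_index = d)
  }
}

# deterministic file naming for the split/merge layout
dest_name <- function(dest) {
  ifelse(dest < 0L, "chrI", sprintf("s%05d", dest))
}

split_path <- function(workdir, input, dest) {
  file.path(workdir, "split", sprintf("%03d__%s.sam", input, dest_name(dest)))
}

merged_path <- function(workdir, dest) {
  file.path(workdir, "merged", sprintf("%s.sam", dest_name(dest)))
}

#' Split one aligned input into per-destination fragments
#'
#' Writes each record of `records` to the fragment file of its routing
#' destination under `workdir/split/<input>__<dest>.sam`. Fragments are
#' canonically sorted; destinations with zero records get no file.
#'
#' @param records records data.table (one input's alignments).
#' @param plan a [partition_genome()] plan.
#' @param input 0-based input ordinal (used in file naming).
#' @param workdir working directory root.
#' @param genome [genome_index()] for headers and sorting.
#' @return A data.table manifest: `input`, `dest`, `path`, `n`.
#' @export
split_alignment_file <- function(records, plan, input, workdir, genome) {
  dir.create(file.path(workdir, "split"), recursive = TRUE,
             showWarnings = FALSE)
  dest <- route_records(records, plan)
  out <- list()
  for (d in sort(unique(dest))) {
    frag <- sort_records(records[dest == d], genome)
    p <- split_path(workdir, input, d)
    write_sam(frag, p, genome = genome)
    out[[length(out) + 1L]] <- data.table::data.table(
      input = input, dest = d, path = p, n = nrow(frag))
  }
  if (length(out) == 0L) {
    return(data.table::data.table(input = integer(), dest = integer(),
                                  path = character(), n = integer()))
  }
  data.table::rbindlist(out)
}

#' Merge split fragments into one per-destination file
#'
#' Concatenates every input's fragment for `dest`, canonically sorts,
#' and writes `workdir/merged/<dest>.sam`. The byte output is
#' independent of fragment arrival order because the sort key covers
#' every record field.
#'
#' @param manifest manifest rows from [split_alignment_file()] (all
#'   inputs).
#' @param dest destination ordinal (`-1L` for `chrI`).
#' @param workdir working directory root.
#' @param genome [genome_index()].
#' @return Path of the merged file.
#' @export
merge_by_destination <- function(manifest, dest, workdir, genome) {
  dir.create(file.path(workdir, "merged"), recursive = TRUE,
             showWarnings = FALSE)
  sel <- manifest[["dest"]] == dest   # plain vector: no column capture
  rows <- manifest[sel, ]
  missing <- rows$path[!file.exists(rows$path)]
  if (length(missing)) {
    stop("integrity error: missing split fragment ", missing[1],
         call. = FALSE)
  }
  recs <- if (nrow(rows)) {
    data.table::rbindlist(lapply(sort(rows$path), read_sam))
  } else {
    empty_records()
  }
  p <- merged_path(workdir, dest)
  write_sam(sort_records(recs, genome), p, genome = genome)
  p
}

#' Redistribute deduplicated chrI reads to their subregions
#'
#' After the `chrI` file has been deduplicated as a unit, each
#' *individual* read is appended to the subregion whose fixed
#' boundaries contain the read's own unclipped 5' position (its mate
#' usually lands elsewhere). Unmapped records have no coordinates and
#' are returned separately (`unplaced`); the caller keeps them in the
#' retained `chrI` copy and in the final merged output.
#'
#' @param chrI_records deduplicated `chrI` records.
#' @param plan a [partition_genome()] plan.
#' @return A list: `assignments` (integer subregion per mapped record,
#'   `NA` for unplaced), `placed` (records with a `.dest` column),
#'   `unplaced` (unmapped records).
#' @export
redistribute_chrI <- function(chrI_records, plan) {
  if (nrow(chrI_records) == 0L) {
    placed <- empty_records()
    placed[, .dest := integer()]
    return(list(assignments = integer(0), placed = placed,
                unplaced = empty_records()))
  }
  mapped <- !is_unmapped(chrI_records$flag)
  assignments <- rep(NA_integer_, nrow(chrI_records))
  if (any(mapped)) {
    u5 <- unclipped_five_prime(chrI_records[mapped])
    s <- locate_subregion(plan, u5$chrom, u5$pos5)
    if (anyNA(s)) {
      i <- which(is.na(s))[1]
      stop(sprintf(
        "integrity error: chrI read %s at %s:%s lies outside all subregions",
        chrI_records$qname[mapped][i], u5$chrom[i], format_bp(u5$pos5[i])),
        call. = FALSE)
    }
    assignments[mapped] <- s
  }
  placed <- data.table::copy(chrI_records[mapped])
  placed[, .dest := assignments[mapped]]
  list(assignments = assignments, placed = placed,
       unplaced = chrI_records[!mapped])
}
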